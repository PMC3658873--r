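## Expression matrix ingest and profile arithmetic shared by the
## co-expression map and the heatmap viewer.

#' Read a gene x condition expression matrix
#'
#' Reads a delimited text matrix: first column gene ids, header row
#' condition ids. The delimiter is auto-detected among tab and comma.
#'
#' @param path Path to the matrix file.
#' @return A numeric matrix with gene ids as rownames and condition ids as
#'   colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("expression matrix not found: ", path)
  first <- readLines(path, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) stop("non-numeric values in expression matrix: ", path)
  if (anyNA(m)) stop("missing values in expression matrix: ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate gene ids in: ", path)
  if (anyDuplicated(colnames(m))) stop("duplicate condition ids in: ", path)
  m
}

#' Co-expression dissimilarity between two profiles
#'
#' Correlation distance `1 - Pearson r`: 0 for perfectly co-regulated
#' profiles, 2 for perfectly anti-correlated ones. Profile *shape* is what
#' co-regulation means, so correlation is the default; Euclidean distance
#' is available for callers that care about magnitude.
#'
#' @param a,b Numeric profile vectors of equal length >= 2.
#' @param method `"pearson"` (default) or `"euclidean"`.
#' @return Dissimilarity in `[0, 2]` for Pearson, `>= 0` for Euclidean.
#' @export
#' @examples
#' expression_distance(c(1, 2, 3), c(2, 4, 6))  # 0: same shape
expression_distance <- function(a, b, method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (method == "euclidean") return(sqrt(sum((a - b)^2)))
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("correlation distance undefined for constant profiles")
  }
  1 - stats::cor(a, b)
}

#' Pairwise co-expression distance matrix
#'
#' @param m Numeric matrix, profiles in rows.
#' @inheritParams expression_distance
#' @return A [stats::dist] object over rows of `m`.
#' @export
expression_dist <- function(m, method = c("pearson", "euclidean")) {
  method <- match.arg(method)
  if (method == "euclidean") return(stats::dist(m))
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    stop("correlation distance undefined for constant profiles: ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  }
  stats::as.dist(1 - stats::cor(t(m)))
}

#' Aggregate expression profiles
#'
#' Element-wise arithmetic mean; the profile drawn on a cluster's glyph.
#'
#' @param profiles Matrix with member profiles in rows (>= 1 row).
#' @return Numeric mean profile.
#' @export
aggregate_profile <- function(profiles) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (nrow(profiles) == 0) stop("cannot aggregate an empty profile set")
  colMeans(profiles)
}
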