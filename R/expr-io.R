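#' Read a gene expression matrix from a tab-separated file
#'
#' Reads a genes x replicates expression table: first column gene symbol,
#' header row of replicate labels, tab-delimited, UTF-8. Empty cells and
#' `NA` are recorded as missing values. Row order is preserved.
#'
#' @param path Path to a tab-separated expression file.
#' @return A numeric matrix with gene symbols as row names and replicate
#'   labels as column names.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' m <- matrix(rnorm(12), 3, 4,
#'             dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
#' write_expression(m, tf)
#' x <- load_expression(tf)
#' stopifnot(identical(dim(x), c(3L, 4L)))
#' @export
load_expression <- function(path) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2L)
    stop("expression file must have a gene column plus >=1 replicate column")
  genes <- raw[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup) > 0L)
    stop("duplicate gene symbol(s) in expression file: ",
         paste(unique(dup), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("non-numeric cell at gene '%s', replicate '%s'",
                 genes[bad[1L, 1L]], colnames(vals)[bad[1L, 2L]]))
  dimnames(num) <- list(genes, colnames(vals))
  validate_expression(num)
  num
}

#' Write an expression matrix to a tab-separated file
#'
#' @param x Numeric matrix with gene row names and replicate column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(gene = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

validate_expression <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop("expression matrix needs unique gene row names")
  n_obs <- rowSums(!is.na(x))
  if (any(n_obs < 3L))
    stop("every gene needs >=3 non-missing replicate values; offender: ",
         rownames(x)[which(n_obs < 3L)[1L]])
  invisible(x)
}

#' Pairwise Pearson correlation between genes
#'
#' Computes the gene x gene Pearson correlation matrix over replicates
#' (pairwise-complete observations, so sparse missingness does not drop
#' whole genes). Constant rows get correlation 0 against everything, so
#' that downstream absolute-correlation thresholding treats them as
#' unconnected; affected genes are recorded in the `"constant_genes"`
#' attribute. Pairs with fewer than 3 complete replicate pairs are set
#' missing (`NA`) and counted in the `"n_incomplete_pairs"` attribute.
#'
#' @param x Expression matrix (genes x replicates) as from
#'   [load_expression()].
#' @return Symmetric correlation matrix with unit diagonal, gene names on
#'   both dimensions.
#' @export
pearson_correlation <- function(x) {
  validate_expression(x)
  r <- suppressWarnings(stats::cor(t(x), use = "pairwise.complete.obs"))
  sds <- apply(x, 1L, stats::sd, na.rm = TRUE)
  const <- which(!is.finite(sds) | sds == 0)
  if (length(const) > 0L) {
    r[const, ] <- 0
    r[, const] <- 0
    warning("constant expression row(s) set to correlation 0: ",
            paste(rownames(x)[const], collapse = ", "))
  }
  obs <- !is.na(x)
  npair <- obs %*% t(obs)
  few <- npair < 3L
  diag(few) <- FALSE
  if (any(few)) r[few] <- NA_real_
  diag(r) <- 1
  r[!is.na(r)] <- pmin(1, pmax(-1, r[!is.na(r)]))
  structure(r,
            constant_genes = rownames(x)[const],
            n_incomplete_pairs = sum(few) / 2)
}
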