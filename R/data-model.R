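#' Read per-CpG methylation counts for one targeted region
#'
#' Reads a long-format tab-separated file with header columns
#' `SampleID`, `Position`, `Total`, `Meth`: one row per sample and CpG site,
#' holding the genomic position (bp), the total read depth and the number of
#' methylated reads. Sites with `Total = 0` carry no likelihood information
#' (the model conditions on read depth) and are dropped with a message.
#'
#' @param path Path to the counts TSV.
#' @return An object of class `meth_counts`: a `data.frame` with columns
#'   `sample_id`, `position`, `total`, `meth`, positions sorted within sample,
#'   plus attributes `region` (position range) and `n_dropped_zero`.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  need <- c("SampleID", "Position", "Total", "Meth")
  if (!all(need %in% names(df)))
    stop("counts file must have header columns SampleID, Position, Total, Meth; found: ",
         paste(names(df), collapse = ", "))
  num <- function(col, what) {
    x <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(x) | (what != "pos" & (x < 0 | x != floor(x))))
    if (length(bad))
      stop("malformed ", col, " in counts file at data line ", bad[1],
           ": '", df[[col]][bad[1]], "'")
    x
  }
  out <- data.frame(
    sample_id = as.character(df$SampleID),
    position  = as.integer(num("Position", "pos")),
    total     = as.integer(num("Total", "count")),
    meth      = as.integer(num("Meth", "count")),
    stringsAsFactors = FALSE
  )
  meth_counts(out)
}

#' Construct and validate a `meth_counts` object
#'
#' @param df data.frame with columns `sample_id`, `position`, `total`, `meth`.
#' @return Validated `meth_counts` object (see [read_counts()]).
#' @export
meth_counts <- function(df) {
  stopifnot(all(c("sample_id", "position", "total", "meth") %in% names(df)))
  bad <- which(df$meth > df$total)
  if (length(bad))
    stop("methylated count exceeds total at record for sample '",
         df$sample_id[bad[1]], "' position ", df$position[bad[1]])
  if (any(df$meth < 0) || any(df$total < 0))
    stop("negative counts are not allowed")
  n_zero <- sum(df$total == 0)
  if (n_zero > 0) {
    message("dropping ", n_zero, " record(s) with zero read depth")
    df <- df[df$total > 0, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no records with positive read depth")
  dup <- duplicated(df[c("sample_id", "position")])
  if (any(dup))
    stop("duplicated position within sample '", df$sample_id[which(dup)[1]],
         "': ", df$position[which(dup)[1]])
  df <- df[order(match(df$sample_id, unique(df$sample_id)), df$position), ,
           drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            region = range(df$position),
            n_dropped_zero = n_zero,
            class = c("meth_counts", "data.frame"))
}

#' Write a `meth_counts` object back to the counts TSV dialect
#'
#' @param counts A `meth_counts` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(SampleID = counts$sample_id, Position = counts$position,
                   Total = counts$total, Meth = counts$meth)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the per-sample covariate table
#'
#' Tab-separated file with header `SampleID` followed by one numeric column
#' per covariate. Column order defines the covariate index used throughout
#' (effect curves, tests).
#'
#' @param path Path to the covariates TSV.
#' @return A `meth_covariates` object: data.frame with `sample_id` plus the
#'   numeric covariate columns.
#' @export
read_covariates <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE)
  if (!"SampleID" %in% names(df))
    stop("covariates file must have a SampleID column")
  covnames <- setdiff(names(df), "SampleID")
  if (length(covnames) == 0L) stop("covariates file has no covariate columns")
  out <- data.frame(sample_id = as.character(df$SampleID),
                    stringsAsFactors = FALSE)
  for (cn in covnames) {
    x <- suppressWarnings(as.numeric(df[[cn]]))
    bad <- which(is.na(x))
    if (length(bad))
      stop("non-numeric value in covariate '", cn, "' at data line ", bad[1],
           ": '", df[[cn]][bad[1]], "'")
    out[[cn]] <- x
  }
  meth_covariates(out)
}

#' Construct and validate a `meth_covariates` object
#'
#' @param df data.frame with column `sample_id` and numeric covariate columns.
#' @return Validated `meth_covariates` object.
#' @export
meth_covariates <- function(df) {
  stopifnot("sample_id" %in% names(df))
  dup <- duplicated(df$sample_id)
  if (any(dup)) stop("duplicated SampleID: ", df$sample_id[which(dup)[1]])
  covnames <- setdiff(names(df), "sample_id")
  for (cn in covnames) {
    if (!is.numeric(df[[cn]])) stop("covariate '", cn, "' is not numeric")
    if (anyNA(df[[cn]])) stop("missing value in covariate '", cn, "'")
  }
  rownames(df) <- NULL
  structure(df, class = c("meth_covariates", "data.frame"))
}

#' Error rates of the read-level observation channel
#'
#' `p0` is the probability that a truly unmethylated read is called
#' methylated (false methylation call); `1 - p1` is the probability that a
#' truly methylated read is called unmethylated. `p0 < p1` strictly is
#' required for the latent methylation proportion to be identifiable.
#'
#' @param p0 False methylation call rate, in `[0, 1)`.
#' @param p1 One minus the false non-methylation call rate, in `(0, 1]`.
#' @return An `error_rates` object (list with `p0`, `p1`).
#' @export
error_rates <- function(p0, p1) {
  stopifnot(is.numeric(p0), is.numeric(p1), length(p0) == 1, length(p1) == 1)
  if (is.na(p0) || is.na(p1) || p0 < 0 || p1 > 1 || p0 >= p1)
    stop("error rates must satisfy 0 <= p0 < p1 <= 1 (got p0=", p0,
         ", p1=", p1, ")")
  structure(list(p0 = p0, p1 = p1), class = "error_rates")
}

#' Join counts with covariates in canonical model order
#'
#' Produces the stacked (sample, position) view that defines the row order of
#' the design matrix: samples in covariate-table order, positions ascending
#' within sample. The joined view is invariant to the row order of the input
#' files.
#'
#' @param counts A `meth_counts` object.
#' @param covariates A `meth_covariates` object covering exactly the samples
#'   present in `counts`.
#' @return A `meth_view` list: `data` (ordered records), `Z` (N x P covariate
#'   matrix), `sample_ids`, `row_sample` (index of each record's sample),
#'   `m_i` (per-sample site counts), `positions` (pooled sorted unique),
#'   `region`.
#' @export
align_region <- function(counts, covariates) {
  s_counts <- unique(counts$sample_id)
  s_cov <- covariates$sample_id
  miss_cov <- setdiff(s_counts, s_cov)
  miss_cnt <- setdiff(s_cov, s_counts)
  if (length(miss_cov) || length(miss_cnt))
    stop("sample sets differ between counts and covariates; ",
         if (length(miss_cov)) paste0("missing covariates for: ",
                                      paste(miss_cov, collapse = ", "), ". "),
         if (length(miss_cnt)) paste0("missing counts for: ",
                                      paste(miss_cnt, collapse = ", ")))
  ord_sample <- s_cov
  df <- as.data.frame(counts)
  df <- df[order(match(df$sample_id, ord_sample), df$position), , drop = FALSE]
  rownames(df) <- NULL
  covnames <- setdiff(names(covariates), "sample_id")
  Z <- as.matrix(as.data.frame(covariates)[covnames])
  rownames(Z) <- ord_sample
  if (ncol(Z) > 0) {
    degen <- covnames[apply(Z, 2, function(z) stats::var(z) == 0)]
    if (length(degen))
      stop("covariate(s) with zero variance: ", paste(degen, collapse = ", "))
  }
  structure(list(
    data = df,
    Z = Z,
    sample_ids = ord_sample,
    row_sample = match(df$sample_id, ord_sample),
    m_i = as.vector(table(factor(df$sample_id, levels = ord_sample))),
    positions = sort(unique(df$position)),
    region = range(df$position)
  ), class = "meth_view")
}
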