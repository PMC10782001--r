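# Transforms from AlphaFold2 outputs to disorder propensity profiles:
# 1 - pLDDT/100, windowed relative solvent accessibility, and selection of
# the best of the five ranked structure models.

#' Maximum Gly-X-Gly accessible surface areas
#'
#' Returns the per-residue maximum accessible surface area (square Angstroms)
#' of residue X in a fully extended Gly-X-Gly tripeptide, used to normalize
#' ASA into relative solvent accessibility. The packaged table holds the
#' theoretical values of Tien et al. (2013); a custom two-column TSV
#' (residue letter, value) may be supplied instead.
#'
#' @param path Optional path to a replacement table.
#' @return Named numeric vector over the 20 standard amino-acid letters.
#' @export
max_asa_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "max_asa_gly_x_gly.tsv", package = "idrbench",
                        mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           col.names = c("res", "max_asa"),
                           colClasses = c("character", "numeric"))
  vals <- stats::setNames(tab$max_asa, tab$res)
  aa <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  if (!all(aa %in% names(vals)))
    stop("max-ASA table must cover all 20 standard amino acids", call. = FALSE)
  if (any(vals <= 0))
    stop("max-ASA values must be strictly positive", call. = FALSE)
  vals[aa]
}

#' Convert pLDDT confidence to disorder propensity
#'
#' The per-residue disorder propensity is `1 - pLDDT/100`: low structural
#' confidence maps to high disorder. Strictly order-reversing in pLDDT.
#'
#' @param plddt A [residue_series] of kind `"plddt"` (values in \[0,100\]).
#' @param method Method label for the resulting profile.
#' @return A [score_profile] with scores in \[0,1\].
#' @export
plddt_to_disorder <- function(plddt, method = "AF2-pLDDT") {
  stopifnot(inherits(plddt, "residue_series"))
  if (plddt$kind != "plddt")
    stop("expected a residue_series of kind 'plddt'", call. = FALSE)
  if (any(plddt$values < 0 | plddt$values > 100))
    stop("pLDDT values outside [0,100]", call. = FALSE)
  score_profile(plddt$id, method, 1 - plddt$values / 100)
}

#' Normalize ASA to relative solvent accessibility
#'
#' Divides each residue's accessible surface area by the maximum
#' accessibility of that residue type in an extended Gly-X-Gly tripeptide,
#' capping at 1. Unknown residue letter `X` is normalized by the mean of the
#' 20 table values (with a warning); any other letter is an error.
#'
#' @param asa A [residue_series] of kind `"asa"`.
#' @param sequence Amino-acid sequence matching the series.
#' @param max_asa Named numeric vector as returned by [max_asa_table()].
#' @return A [residue_series] of kind `"rsa"`.
#' @export
asa_to_rsa <- function(asa, sequence, max_asa = max_asa_table()) {
  stopifnot(inherits(asa, "residue_series"))
  if (asa$kind != "asa") stop("expected a residue_series of kind 'asa'", call. = FALSE)
  res <- strsplit(toupper(sequence), "")[[1]]
  if (length(res) != length(asa$values))
    stop(sprintf("series '%s': sequence length %d does not match ASA length %d",
                 asa$id, length(res), length(asa$values)), call. = FALSE)
  unknown <- setdiff(unique(res), c(names(max_asa), "X"))
  if (length(unknown))
    stop(sprintf("series '%s': unknown residue letter(s) %s",
                 asa$id, paste(unknown, collapse = ",")), call. = FALSE)
  denom <- unname(max_asa[res])
  if (any(res == "X")) {
    warning(sprintf("series '%s': residue letter X normalized by the table mean",
                    asa$id), call. = FALSE)
    denom[res == "X"] <- mean(max_asa)
  }
  residue_series(asa$id, pmin(1, asa$values / denom), "rsa")
}

# Running mean with window truncated at the termini: value i is the mean of
# the series over [i-w, i+w] intersected with [1, L].
running_mean <- function(x, window) {
  L <- length(x)
  if (L == 0L) return(numeric())
  w <- (window - 1L) %/% 2L
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(L) - w, 1L)
  hi <- pmin(seq_len(L) + w, L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth an RSA series into a disorder propensity profile
#'
#' Applies a sliding arithmetic mean of odd width `window` (default 25),
#' truncated at the sequence termini, to a relative-solvent-accessibility
#' series. Persistently elevated accessibility marks disordered regions.
#'
#' @param rsa A [residue_series] of kind `"rsa"`.
#' @param window Odd window size, default 25.
#' @param method Method label for the resulting profile.
#' @return A [score_profile].
#' @export
smooth_rsa <- function(rsa, window = 25L, method = "AF2-RSA") {
  stopifnot(inherits(rsa, "residue_series"))
  if (rsa$kind != "rsa") stop("expected a residue_series of kind 'rsa'", call. = FALSE)
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be odd and >= 1", call. = FALSE)
  score_profile(rsa$id, method, running_mean(rsa$values, window))
}

#' Select the most accurate of the ranked structure models
#'
#' AlphaFold2 emits up to five ranked structure models. Given the disorder
#' profiles derived from each model (in native rank order) and the reference
#' labels, returns the profile with the highest per-protein ROC AUC; ties go
#' to the lower native rank. This is the optimized-rank scenario: a
#' hypothetical re-ranking of the models by disorder prediction quality.
#'
#' @param ranks List of [score_profile] objects in native rank order (1-5).
#' @param reference The matching [ref_entry]; must contain at least one
#'   disordered and one ordered residue, otherwise AUC is undefined and the
#'   protein must be excluded.
#' @return The selected [score_profile], with attribute `"rank"`.
#' @export
select_best_model <- function(ranks, reference) {
  stopifnot(is.list(ranks), length(ranks) >= 1L, length(ranks) <= 5L,
            inherits(reference, "ref_entry"))
  lens <- vapply(ranks, function(p) length(p$scores), 0L)
  if (length(unique(lens)) != 1L)
    stop("ranked profiles differ in length", call. = FALSE)
  y <- reference$disorder
  if (sum(y) == 0L || sum(y) == length(y))
    stop(sprintf("record '%s': AUC undefined (single-class labels); exclude this protein",
                 reference$id), call. = FALSE)
  aucs <- vapply(ranks, function(p) roc_auc(p$scores, y), 0)
  best <- which.max(aucs)   # which.max keeps the lowest index on ties
  out <- ranks[[best]]
  attr(out, "rank") <- best
  attr(out, "auc") <- aucs[best]
  out
}
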