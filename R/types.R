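#' Reference entry constructor
#'
#' A reference entry holds one benchmark protein: its accession, amino-acid
#' sequence, per-residue disorder labels and (optionally) per-residue binding
#' labels. Labels are integer 0/1 vectors aligned to the sequence.
#'
#' @param id Accession string.
#' @param sequence Amino-acid sequence (single string).
#' @param disorder Integer 0/1 vector, one value per residue.
#' @param binding Optional integer 0/1 vector of the same length.
#' @return An object of class `ref_entry`.
#' @export
ref_entry <- function(id, sequence, disorder, binding = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  L <- nchar(sequence)
  disorder <- as.integer(disorder)
  if (length(disorder) != L)
    stop(sprintf("record '%s': disorder labels (%d) do not match sequence length (%d)",
                 id, length(disorder), L), call. = FALSE)
  if (!all(disorder %in% c(0L, 1L)))
    stop(sprintf("record '%s': disorder labels outside {0,1}", id), call. = FALSE)
  if (!is.null(binding)) {
    binding <- as.integer(binding)
    if (length(binding) != L)
      stop(sprintf("record '%s': binding labels (%d) do not match sequence length (%d)",
                   id, length(binding), L), call. = FALSE)
    if (!all(binding %in% c(0L, 1L)))
      stop(sprintf("record '%s': binding labels outside {0,1}", id), call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, disorder = disorder,
                 binding = binding), class = "ref_entry")
}

#' @export
print.ref_entry <- function(x, ...) {
  cat(sprintf("<ref_entry> %s  L=%d  disorder=%d%s\n", x$id, nchar(x$sequence),
              sum(x$disorder),
              if (is.null(x$binding)) "" else sprintf("  binding=%d", sum(x$binding))))
  invisible(x)
}

#' Score profile constructor
#'
#' Per-residue real-valued disorder propensities in \[0,1\] for one protein
#' from one method, with optional binary calls.
#'
#' @param id Accession string.
#' @param method Method name.
#' @param scores Numeric vector of propensities in \[0,1\].
#' @param binary Optional integer 0/1 vector of the same length.
#' @return An object of class `score_profile`.
#' @export
score_profile <- function(id, method, scores, binary = NULL) {
  scores <- as.numeric(scores)
  if (any(!is.finite(scores)))
    stop(sprintf("profile '%s': non-finite scores", id), call. = FALSE)
  if (any(scores < 0 | scores > 1))
    stop(sprintf("profile '%s': scores outside [0,1]", id), call. = FALSE)
  if (!is.null(binary)) {
    binary <- as.integer(binary)
    if (length(binary) != length(scores))
      stop(sprintf("profile '%s': binary length mismatch", id), call. = FALSE)
    if (!all(binary %in% c(0L, 1L)))
      stop(sprintf("profile '%s': binary values outside {0,1}", id), call. = FALSE)
  }
  structure(list(id = id, method = method, scores = scores, binary = binary),
            class = "score_profile")
}

#' @export
print.score_profile <- function(x, ...) {
  cat(sprintf("<score_profile> %s [%s]  L=%d  binary=%s\n", x$id, x$method,
              length(x$scores), if (is.null(x$binary)) "no" else "yes"))
  invisible(x)
}

#' Residue series constructor
#'
#' A per-residue numeric series of a declared kind: `plddt` (AlphaFold2
#' confidence, 0-100), `asa` (accessible surface area, A^2, >= 0) or `rsa`
#' (relative solvent accessibility, \[0,1\]).
#'
#' @param id Accession string.
#' @param values Numeric vector.
#' @param kind One of `"plddt"`, `"asa"`, `"rsa"`.
#' @return An object of class `residue_series`.
#' @export
residue_series <- function(id, values, kind = c("plddt", "asa", "rsa")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (any(!is.finite(values)) && length(values))
    stop(sprintf("series '%s': non-finite values", id), call. = FALSE)
  ok <- switch(kind,
    plddt = all(values >= 0 & values <= 100),
    asa   = all(values >= 0),
    rsa   = all(values >= 0 & values <= 1))
  if (!ok)
    stop(sprintf("series '%s': values outside the valid range for kind '%s'",
                 id, kind), call. = FALSE)
  structure(list(id = id, values = values, kind = kind), class = "residue_series")
}

#' @export
print.residue_series <- function(x, ...) {
  cat(sprintf("<residue_series> %s  kind=%s  L=%d\n", x$id, x$kind, length(x$values)))
  invisible(x)
}
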