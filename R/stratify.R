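# IDR segmentation and the protein subsets used in the comparative analysis:
# shortIDR, longIDR, bindingIDR, non-terminusIDR and the fully-disordered
# FDP99/FDP90/FDP80 sets.

#' Extract intrinsically disordered regions from a label series
#'
#' Maximal runs of 1-labels with length at least `min_len`, as a data frame
#' of 1-based inclusive coordinates in ascending start order. A segment is at
#' a terminus when it includes residue 1 or residue L. Native disordered
#' regions use `min_len = 1`; putative regions in the marker analysis use
#' `min_len = 4`.
#'
#' @param labels Integer 0/1 vector.
#' @param min_len Minimum run length kept, default 1.
#' @return Data frame with columns `start`, `end`, `length`, `at_terminus`,
#'   `binding` (initialized `NA`).
#' @export
extract_idrs <- function(labels, min_len = 1L) {
  labels <- as.integer(labels)
  if (length(labels) && !all(labels %in% c(0L, 1L)))
    stop("labels outside {0,1}", call. = FALSE)
  L <- length(labels)
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == 1L & r$lengths >= min_len
  out <- data.frame(start = starts[keep], end = ends[keep],
                    length = r$lengths[keep])
  out$at_terminus <- out$start == 1L | out$end == L
  out$binding <- rep(NA, nrow(out))
  out
}

#' Flag binding regions at the segment level
#'
#' A disordered region counts as binding when any of its residues carries a
#' binding annotation: binding is annotated for entire regions even when
#' only part of the region contacts the partner.
#'
#' @param segments Data frame from [extract_idrs()].
#' @param binding Integer 0/1 per-residue binding labels.
#' @return The segments with the `binding` column filled.
#' @export
flag_binding <- function(segments, binding) {
  binding <- as.integer(binding)
  segments$binding <- vapply(seq_len(nrow(segments)), function(k) {
    any(binding[segments$start[k]:segments$end[k]] == 1L)
  }, TRUE)
  segments
}

# Segments for one entry with binding flags filled where labels exist.
entry_idrs <- function(entry, min_len = 1L) {
  seg <- extract_idrs(entry$disorder, min_len)
  if (!is.null(entry$binding)) seg <- flag_binding(seg, entry$binding)
  else seg$binding <- rep(FALSE, nrow(seg))
  seg
}

#' Assign proteins to the comparison datasets
#'
#' Builds the membership map over the tags: `CAID` (every protein),
#' `shortIDR` (at least one IDR and all IDRs of length <= 30), `longIDR` (at
#' least one IDR longer than 30 residues), `bindingIDR` (at least one
#' binding-flagged IDR), `non-terminusIDR` (at least one IDR and none
#' touching residue 1 or L), and `FDP99`/`FDP90`/`FDP80` (disorder content
#' strictly above 0.99/0.90/0.80).
#'
#' @param entries Named list of [ref_entry] objects.
#' @param long_cutoff Length above which an IDR counts as long, default 30.
#' @return Object of class `dataset_membership`: a named list mapping protein
#'   id to its tag set, with attribute `"datasets"` listing all tags.
#' @export
build_datasets <- function(entries, long_cutoff = 30L) {
  tags_all <- c("CAID", "shortIDR", "longIDR", "bindingIDR", "non-terminusIDR",
                "FDP99", "FDP90", "FDP80")
  membership <- lapply(entries, function(e) {
    seg <- entry_idrs(e)
    tags <- "CAID"
    if (nrow(seg)) {
      if (all(seg$length <= long_cutoff)) tags <- c(tags, "shortIDR")
      if (any(seg$length > long_cutoff)) tags <- c(tags, "longIDR")
      if (any(seg$binding)) tags <- c(tags, "bindingIDR")
      if (!any(seg$at_terminus)) tags <- c(tags, "non-terminusIDR")
    }
    content <- disorder_content(e$disorder)
    if (content > 0.99) tags <- c(tags, "FDP99")
    if (content > 0.90) tags <- c(tags, "FDP90")
    if (content > 0.80) tags <- c(tags, "FDP80")
    tags
  })
  structure(membership, class = "dataset_membership", datasets = tags_all,
            long_cutoff = long_cutoff)
}

#' Protein identifiers carrying a dataset tag
#'
#' @param membership A `dataset_membership` from [build_datasets()].
#' @param tag Dataset tag.
#' @return Character vector of protein ids.
#' @export
membership_ids <- function(membership, tag) {
  names(membership)[vapply(membership, function(t) tag %in% t, TRUE)]
}

#' Summarize the comparison datasets
#'
#' One row per dataset: number of member proteins, number of qualifying IDRs,
#' number of disordered residues in those IDRs, and the median qualifying IDR
#' length. The qualifying IDRs are the ones that define the dataset: the
#' short IDRs for `shortIDR`, the binding IDRs for `bindingIDR`, and all IDRs
#' of member proteins otherwise.
#'
#' @param membership A `dataset_membership`.
#' @param entries The named list of [ref_entry] objects it was built from.
#' @return Data frame with columns `dataset`, `n_proteins`, `n_idrs`,
#'   `n_disordered_residues`, `median_idr_length`.
#' @export
dataset_summary <- function(membership, entries) {
  long_cutoff <- attr(membership, "long_cutoff")
  segs <- lapply(entries, entry_idrs)
  rows <- lapply(attr(membership, "datasets"), function(tag) {
    ids <- membership_ids(membership, tag)
    if (!length(ids))
      return(data.frame(dataset = tag, n_proteins = 0L, n_idrs = 0L,
                        n_disordered_residues = 0L, median_idr_length = NA_real_))
    lens <- unlist(lapply(ids, function(i) {
      s <- segs[[i]]
      if (tag == "shortIDR") s <- s[s$length <= long_cutoff, , drop = FALSE]
      if (tag == "bindingIDR") s <- s[s$binding, , drop = FALSE]
      s$length
    }), use.names = FALSE)
    data.frame(dataset = tag, n_proteins = length(ids),
               n_idrs = length(lens),
               n_disordered_residues = sum(lens),
               median_idr_length = if (length(lens)) stats::median(lens) else NA_real_)
  })
  do.call(rbind, rows)
}
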