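# Readers and writers for the external formats the pipeline touches:
# CAID-style reference files (FASTA-like, 0/1 annotation line), CAID-style
# per-residue prediction files, AlphaFold2 PDB models (pLDDT in the
# temperature-factor column) and per-residue ASA tables.

#' Read a CAID-style disorder reference file
#'
#' Each record is a `>` header line, one or more sequence lines, then an
#' annotation line of identical total length over \{0,1\} (1 = disordered).
#' The identifier is the header token before the first whitespace. A second
#' file of the same dialect may supply per-residue binding labels, which are
#' joined onto matching identifiers; binding-file entries with no matching
#' disorder entry are skipped with a warning.
#'
#' @param path Path to the disorder reference file.
#' @param binding_path Optional path to the binding reference file.
#' @return A named list of [ref_entry] objects, in file order.
#' @export
read_reference <- function(path, binding_path = NULL) {
  entries <- parse_reference_file(path)
  if (!is.null(binding_path)) {
    bind <- parse_reference_file(binding_path)
    extra <- setdiff(names(bind), names(entries))
    if (length(extra))
      warning(sprintf("binding file: %d entrie(s) with no matching disorder record ignored (%s%s)",
                      length(extra), paste(utils::head(extra, 3), collapse = ", "),
                      if (length(extra) > 3) ", ..." else ""), call. = FALSE)
    for (id in intersect(names(bind), names(entries))) {
      b <- bind[[id]]
      e <- entries[[id]]
      if (nchar(b$sequence) != nchar(e$sequence))
        stop(sprintf("record '%s': binding file length %d does not match disorder file length %d",
                     id, nchar(b$sequence), nchar(e$sequence)), call. = FALSE)
      entries[[id]]$binding <- b$disorder
    }
  }
  entries
}

# Parse one FASTA-like file with a trailing 0/1 annotation block per record.
# Lines made only of 0/1 characters at the end of a record are the annotation;
# the preceding lines are sequence (amino-acid letters never collide with 0/1).
parse_reference_file <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !startsWith(lines[[1]], ">"))
    stop(sprintf("%s: not a reference file (no '>' header)", path), call. = FALSE)
  head_idx <- which(startsWith(lines, ">"))
  bounds <- c(head_idx, length(lines) + 1L)
  entries <- list()
  for (k in seq_along(head_idx)) {
    header <- sub("^>", "", lines[[head_idx[k]]])
    id <- strsplit(trimws(header), "\\s+")[[1]][1]
    body <- lines[seq.int(head_idx[k] + 1L, bounds[k + 1L] - 1L)]
    body <- trimws(body)
    if (!length(body))
      stop(sprintf("record '%s': empty record", id), call. = FALSE)
    is_annot <- grepl("^[01]+$", body)
    # annotation = maximal trailing run of 0/1-only lines
    n_annot <- 0L
    for (j in rev(seq_along(is_annot))) {
      if (is_annot[j]) n_annot <- n_annot + 1L else break
    }
    if (n_annot == 0L)
      stop(sprintf("record '%s': missing 0/1 annotation line", id), call. = FALSE)
    if (n_annot == length(body))
      stop(sprintf("record '%s': missing sequence lines", id), call. = FALSE)
    seq_part <- paste(body[seq_len(length(body) - n_annot)], collapse = "")
    ann_part <- paste(body[seq.int(length(body) - n_annot + 1L, length(body))],
                      collapse = "")
    if (grepl("[^A-Za-z]", seq_part))
      stop(sprintf("record '%s': non-letter characters in sequence", id), call. = FALSE)
    if (nchar(ann_part) != nchar(seq_part))
      stop(sprintf("record '%s': annotation length %d does not match sequence length %d",
                   id, nchar(ann_part), nchar(seq_part)), call. = FALSE)
    if (id %in% names(entries))
      stop(sprintf("duplicate identifier '%s'", id), call. = FALSE)
    labels <- as.integer(strsplit(ann_part, "")[[1]])
    entries[[id]] <- ref_entry(id, seq_part, labels)
  }
  entries
}

#' Read a CAID-style per-residue prediction file
#'
#' Data lines are whitespace/tab-separated: 1-based position, residue letter,
#' propensity, optional binary call. Files holding several proteins separate
#' them with `>` header lines; a headerless file yields a single profile named
#' after the file. Positions must be contiguous from 1. Scores marginally
#' outside \[0,1\] (excess at most 0.05) are clamped with a warning; larger
#' excursions are an error.
#'
#' @param path Path to the prediction file.
#' @param method Method name attached to the profiles; defaults to the file
#'   name without extension.
#' @return A named list of [score_profile] objects.
#' @export
read_prediction <- function(path, method = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  head_idx <- which(startsWith(lines, ">"))
  if (!length(head_idx)) {
    recs <- list(list(id = method, body = lines))
  } else {
    if (head_idx[1] != 1L)
      stop(sprintf("%s: data lines before the first '>' header", path), call. = FALSE)
    bounds <- c(head_idx, length(lines) + 1L)
    recs <- lapply(seq_along(head_idx), function(k) {
      id <- strsplit(trimws(sub("^>", "", lines[[head_idx[k]]])), "\\s+")[[1]][1]
      body <- if (bounds[k + 1L] - head_idx[k] > 1L)
        lines[seq.int(head_idx[k] + 1L, bounds[k + 1L] - 1L)] else character()
      list(id = id, body = body)
    })
  }
  out <- list()
  for (r in recs) {
    prof <- parse_prediction_body(r$body, r$id, method)
    if (r$id %in% names(out))
      stop(sprintf("duplicate identifier '%s'", r$id), call. = FALSE)
    out[[r$id]] <- prof
  }
  out
}

parse_prediction_body <- function(body, id, method) {
  if (!length(body))
    stop(sprintf("record '%s': empty prediction body", id), call. = FALSE)
  fields <- strsplit(trimws(body), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("record '%s': data line with fewer than 3 fields", id), call. = FALSE)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  if (any(is.na(pos)))
    stop(sprintf("record '%s': unparseable position", id), call. = FALSE)
  if (!identical(pos, seq_along(pos)))
    stop(sprintf("record '%s': positions are not contiguous from 1", id), call. = FALSE)
  scores <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(scores)))
    stop(sprintf("record '%s': unparseable score", id), call. = FALSE)
  excess <- pmax(scores - 1, -scores, 0)
  if (any(excess > 0.05 + 1e-9))
    stop(sprintf("record '%s': score outside [0,1] by more than 0.05", id), call. = FALSE)
  if (any(excess > 0)) {
    warning(sprintf("record '%s': %d score(s) marginally outside [0,1] clamped",
                    id, sum(excess > 0)), call. = FALSE)
    scores <- pmin(1, pmax(0, scores))
  }
  binary <- NULL
  if (all(nf >= 4L)) {
    binary <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L)))
    if (any(is.na(binary)) || !all(binary %in% c(0L, 1L)))
      stop(sprintf("record '%s': unparseable binary call", id), call. = FALSE)
  }
  score_profile(id, method, scores, binary)
}

#' Write score profiles in the CAID prediction dialect
#'
#' Emits one `>` header per profile followed by tab-separated lines of
#' position, residue letter (taken from `sequences` when available, `X`
#' otherwise), score to three decimals and, when present, the binary call.
#' Re-reading the file reproduces scores to three decimals and binary calls
#' exactly, in input order.
#'
#' @param profiles A list of [score_profile] objects.
#' @param path Output path.
#' @param sequences Optional named character vector / list of sequences keyed
#'   by profile id, used to fill the residue-letter column.
#' @export
write_prediction <- function(profiles, path, sequences = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (p in profiles) {
    if (!inherits(p, "score_profile")) stop("profiles must be score_profile objects")
    L <- length(p$scores)
    res <- if (!is.null(sequences) && !is.null(sequences[[p$id]]))
      strsplit(sequences[[p$id]], "")[[1]] else rep("X", L)
    writeLines(paste0(">", p$id), con)
    if (is.null(p$binary)) {
      writeLines(sprintf("%d\t%s\t%.3f", seq_len(L), res, p$scores), con)
    } else {
      writeLines(sprintf("%d\t%s\t%.3f\t%d", seq_len(L), res, p$scores, p$binary), con)
    }
  }
  invisible(path)
}

#' Extract per-residue pLDDT from an AlphaFold2 model in PDB format
#'
#' AlphaFold2 stores the per-residue pLDDT confidence in the temperature
#' factor column of every atom. One value per residue is taken from the
#' alpha-carbon record; residues lacking a CA atom fall back to their first
#' atom, with a warning.
#'
#' @param path Path to the PDB file.
#' @param chain Chain identifier; required when the file holds several chains.
#' @param model Model number; required when the file holds several `MODEL`
#'   blocks.
#' @return A [residue_series] of kind `"plddt"`.
#' @export
read_plddt_from_model <- function(path, chain = NULL, model = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  model_starts <- grep("^MODEL\\b", raw)
  read_path <- path
  if (length(model_starts) > 1L) {
    if (is.null(model))
      stop(sprintf("%s holds %d models; pass `model =` to choose one",
                   path, length(model_starts)), call. = FALSE)
    ends <- grep("^ENDMDL\\b", raw)
    if (model < 1L || model > length(model_starts))
      stop(sprintf("model %d not in file (1..%d)", model, length(model_starts)),
           call. = FALSE)
    block <- raw[seq.int(model_starts[model] + 1L, ends[model] - 1L)]
    read_path <- tempfile(fileext = ".pdb")
    on.exit(unlink(read_path))
    writeLines(c(block, "END"), read_path)
  }
  pdb <- suppressWarnings(bio3d::read.pdb(read_path))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(atoms))
    stop(sprintf("%s: no ATOM records", path), call. = FALSE)
  chains <- unique(atoms$chain)
  if (is.null(chain)) {
    if (length(chains) > 1L)
      stop(sprintf("%s holds chains %s; pass `chain =` to choose one",
                   path, paste(chains, collapse = ",")), call. = FALSE)
    chain <- chains[1]
  }
  atoms <- atoms[atoms$chain == chain, , drop = FALSE]
  if (!nrow(atoms))
    stop(sprintf("%s: no ATOM records for chain %s", path, chain), call. = FALSE)
  resno <- atoms$resno
  res_ids <- unique(resno)
  vals <- numeric(length(res_ids))
  missing_ca <- character()
  for (k in seq_along(res_ids)) {
    rows <- atoms[resno == res_ids[k], , drop = FALSE]
    ca <- rows[rows$elety == "CA", , drop = FALSE]
    if (nrow(ca)) {
      vals[k] <- ca$b[1]
    } else {
      vals[k] <- rows$b[1]
      missing_ca <- c(missing_ca, as.character(res_ids[k]))
    }
  }
  if (length(missing_ca))
    warning(sprintf("%s: residue(s) %s lack a CA atom; first atom used",
                    basename(path), paste(missing_ca, collapse = ",")), call. = FALSE)
  residue_series(tools::file_path_sans_ext(basename(path)), vals, "plddt")
}

#' Read a per-residue accessible-surface-area table
#'
#' Whitespace/tab-separated columns: 1-based position, residue letter, ASA in
#' square Angstroms. Positions must be contiguous from 1 and ASA non-negative.
#' An optional `>` header supplies the identifier.
#'
#' @param path Path to the table.
#' @return A [residue_series] of kind `"asa"`; the residue letters are kept in
#'   attribute `"sequence"`.
#' @export
read_asa_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(lines, "#")]
  id <- tools::file_path_sans_ext(basename(path))
  if (length(lines) && startsWith(lines[1], ">")) {
    id <- strsplit(trimws(sub("^>", "", lines[1])), "\\s+")[[1]][1]
    lines <- lines[-1]
  }
  if (!length(lines)) {
    warning(sprintf("%s: empty ASA table", path), call. = FALSE)
    out <- residue_series(id, numeric(), "asa")
    attr(out, "sequence") <- ""
    return(out)
  }
  fields <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(fields) < 3L))
    stop(sprintf("%s: ASA line with fewer than 3 fields", path), call. = FALSE)
  pos <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 1L)))
  if (any(is.na(pos)) || !identical(pos, seq_along(pos)))
    stop(sprintf("%s: positions are not contiguous from 1", path), call. = FALSE)
  asa <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  if (any(is.na(asa)))
    stop(sprintf("%s: unparseable ASA value", path), call. = FALSE)
  if (any(asa < 0))
    stop(sprintf("%s: negative ASA value", path), call. = FALSE)
  out <- residue_series(id, asa, "asa")
  attr(out, "sequence") <- paste(vapply(fields, `[[`, "", 2L), collapse = "")
  out
}
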