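# Aligned barcode panels: diagnostic columns, common-region trimming,
# ungapped primer anchoring.
#
# Coordinates are 1-based and inclusive on the sense strand of the
# designated reference row. The reference row must be ungapped, so alignment
# columns and reference positions coincide; the map is kept explicit anyway
# so downstream code never relies on that accident. CO1 barcodes are
# protein-coding and effectively indel-free across the taxa this package is
# aimed at, which is why primer anchoring is ungapped sliding-window search.

#' Load an aligned barcode panel
#'
#' @param records panel data.frame (gaps permitted), all rows equal length.
#' @param ref_id id of the reference row; must be ungapped.
#' @return a \code{barcode_alignment} object.
#' @export
load_alignment <- function(records, ref_id) {
  if (nrow(records) == 0L) stop("empty alignment", call. = FALSE)
  lens <- nchar(records$residues)
  if (length(unique(lens)) != 1L) {
    bad <- records$id[lens != stats::median(lens)]
    stop("ragged alignment; offending id(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (!ref_id %in% records$id) {
    stop("ref_id '", ref_id, "' not present in panel", call. = FALSE)
  }
  ref <- records$residues[records$id == ref_id]
  if (grepl("-", ref, fixed = TRUE)) {
    stop("reference row '", ref_id, "' contains gaps", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(records$residues, "", fixed = TRUE))
  rownames(mat) <- records$id
  structure(list(records = records, mat = mat, ref_id = ref_id,
                 ncol = lens[1],
                 col_to_ref = seq_len(lens[1])),
            class = "barcode_alignment")
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat(sprintf("barcode_alignment: %d sequences x %d columns (reference %s)\n",
              nrow(x$mat), x$ncol, x$ref_id))
  invisible(x)
}

#' Find diagnostic alignment columns
#'
#' A column is diagnostic when every target row carries one identical
#' unambiguous base and at least \code{min_nontarget_frac} of the non-target
#' rows carry a different base. These fixed differences are the raw material
#' for species-specific primer 3' termini.
#'
#' @param aln \code{barcode_alignment}.
#' @param target_ids,nontarget_ids disjoint, non-empty id sets.
#' @param min_nontarget_frac fraction of non-target rows that must differ
#'   (default 1: the site must discriminate against the whole panel).
#' @return data.frame: ref_pos, target_base, nontarget_frac_diff, and
#'   nontarget_spectrum ("base:frac" pairs, comma-separated), sorted by
#'   position.
#' @export
diagnostic_sites <- function(aln, target_ids, nontarget_ids,
                             min_nontarget_frac = 1) {
  stopifnot(inherits(aln, "barcode_alignment"))
  if (length(target_ids) == 0L || length(nontarget_ids) == 0L) {
    stop("target and nontarget sets must be non-empty", call. = FALSE)
  }
  if (length(intersect(target_ids, nontarget_ids))) {
    stop("target and nontarget sets overlap", call. = FALSE)
  }
  missing_ids <- setdiff(c(target_ids, nontarget_ids), rownames(aln$mat))
  if (length(missing_ids)) {
    stop("ids not in alignment: ", paste(missing_ids, collapse = ", "),
         call. = FALSE)
  }
  tmat <- aln$mat[target_ids, , drop = FALSE]
  nmat <- aln$mat[nontarget_ids, , drop = FALSE]
  out <- lapply(seq_len(aln$ncol), function(j) {
    tb <- unique(tmat[, j])
    if (length(tb) != 1L || !tb %in% c("A", "C", "G", "T")) return(NULL)
    nb <- nmat[, j]
    frac_diff <- mean(nb != tb)
    if (frac_diff < min_nontarget_frac) return(NULL)
    tab <- table(nb) / length(nb)
    spectrum <- paste(sprintf("%s:%.3g", names(tab), as.numeric(tab)),
                      collapse = ",")
    data.frame(ref_pos = aln$col_to_ref[j], target_base = tb,
               nontarget_frac_diff = frac_diff,
               nontarget_spectrum = spectrum, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(out)) {
    out <- data.frame(ref_pos = integer(), target_base = character(),
                      nontarget_frac_diff = numeric(),
                      nontarget_spectrum = character(),
                      stringsAsFactors = FALSE)
  }
  out[order(out$ref_pos), , drop = FALSE]
}

# Best ungapped offset of `query` against `ref` (both plain ACGT strings,
# same strand): maximizes matches over the overlap. Returns the 1-based ref
# position aligned with query position 1 (may be < 1 for left overhang).
best_ungapped_offset <- function(query, ref, min_overlap = 15L) {
  q <- split_chars(query); r <- split_chars(ref)
  nq <- length(q); nr <- length(r)
  ov <- min(min_overlap, nq, nr)
  starts <- seq(1L - nq + ov, nr - ov + 1L)
  score <- vapply(starts, function(s) {
    i <- seq_len(nq)
    rpos <- s + i - 1L
    keep <- rpos >= 1L & rpos <= nr
    sum(q[i[keep]] == r[rpos[keep]])
  }, numeric(1))
  starts[which.max(score)]
}

#' Trim homologous records to their common region
#'
#' Anchors every record to a reference by exhaustive ungapped offset search,
#' intersects the per-record coverage intervals in reference coordinates,
#' and trims all records to that intersection. Mirrors the routine step of
#' shortening compared barcodes to the stretch every accession covers before
#' haplotype collapse.
#'
#' @param records ungapped panel data.frame, equal or unequal lengths.
#' @param ref_id reference record id (default: the longest record).
#' @param on_partial what to do with a record that does not span the
#'   intersection: "drop" (excluded and reported) or "error".
#' @return list(records = trimmed panel, region = c(start, end) in reference
#'   coordinates, excluded = character ids).
#' @export
trim_to_common_region <- function(records, ref_id = NULL,
                                  on_partial = c("drop", "error")) {
  on_partial <- match.arg(on_partial)
  if (nrow(records) < 2L) stop("need at least two records", call. = FALSE)
  if (is.null(ref_id)) {
    ref_id <- records$id[which.max(nchar(records$residues))]
  }
  ref <- records$residues[records$id == ref_id]
  if (length(ref) != 1L) stop("ref_id not found", call. = FALSE)
  nr <- nchar(ref)
  offs <- vapply(records$residues, best_ungapped_offset, numeric(1),
                 ref = ref, USE.NAMES = FALSE)
  cover_lo <- pmax(offs, 1L)
  cover_hi <- pmin(offs + nchar(records$residues) - 1L, nr)
  s <- max(cover_lo); e <- min(cover_hi)
  if (s > e) stop("records share no common region on the reference",
                  call. = FALSE)
  # records must fully cover [s, e]
  full <- cover_lo <= s & cover_hi >= e
  excluded <- records$id[!full]
  if (length(excluded) && on_partial == "error") {
    stop("record(s) not spanning the common region: ",
         paste(excluded, collapse = ", "), call. = FALSE)
  }
  keep <- records[full, , drop = FALSE]
  offs <- offs[full]
  keep$residues <- vapply(seq_len(nrow(keep)), function(i) {
    substr(keep$residues[i], s - offs[i] + 1L, e - offs[i] + 1L)
  }, character(1))
  list(records = keep, region = c(start = s, end = e), excluded = excluded)
}

#' Anchor a primer on a template by exhaustive mismatch minimization
#'
#' Slides the primer (and its reverse complement) across every offset of the
#' template, counting disagreements; partial overlaps at the template ends
#' are allowed and the uncovered positions counted as missing. A template
#' ambiguity code that includes the primer base counts as a match for
#' anchoring (it is flagged, not penalized). Ties are broken by proximity to
#' \code{ref_hint}, then smallest ref_start, then sense before antisense.
#'
#' @param primer a \code{primer} object (see \code{\link{primer}}) or a plain
#'   5'-to-3' sequence string.
#' @param template a single-row panel data.frame or a sequence string.
#' @param ref_hint optional expected sense-strand 5' coordinate.
#' @param min_overlap minimum primer/template overlap considered (default 10).
#' @return list: template_id, strand ("sense"/"antisense"), ref_start,
#'   ref_end, covered (fraction of primer positions with template data),
#'   mismatches (anchor objective: mismatch + gap + missing).
#' @export
anchor_primer <- function(primer, template, ref_hint = NULL,
                          min_overlap = 10L) {
  pseq <- if (inherits(primer, "primer")) primer$sequence else
    normalize_dna(primer, what = "primer")
  tid <- NA_character_
  tseq <- template
  if (is.data.frame(template)) {
    stopifnot(nrow(template) == 1L)
    tid <- template$id
    tseq <- template$residues
  }
  tseq <- normalize_dna(tseq, allow_gap = TRUE, what = "template")
  plen <- nchar(pseq)
  tlen <- nchar(tseq)
  tchars <- split_chars(tseq)
  scan_one <- function(qseq, strand) {
    q <- split_chars(qseq)
    ov <- min(min_overlap, plen, tlen)
    starts <- seq(1L - plen + ov, tlen - ov + 1L)
    res <- lapply(starts, function(s) {
      i <- seq_len(plen)
      tpos <- s + i - 1L
      inb <- tpos >= 1L & tpos <= tlen
      tb <- rep("", plen)
      tb[inb] <- tchars[tpos[inb]]
      match_ok <- inb & mapply(function(code, base) {
        code != "-" && iupac_contains(code, base)
      }, tb, q)
      mm <- sum(!match_ok)  # mismatch + gap + missing
      list(s = s, mm = mm, covered = mean(inb))
    })
    data.frame(strand = strand,
               s = vapply(res, `[[`, numeric(1), "s"),
               mm = vapply(res, `[[`, numeric(1), "mm"),
               covered = vapply(res, `[[`, numeric(1), "covered"))
  }
  tab <- rbind(scan_one(pseq, "sense"),
               scan_one(reverse_complement(pseq), "antisense"))
  tab$ref_start <- tab$s
  tab$ref_end <- tab$s + plen - 1L
  hint_dist <- if (is.null(ref_hint)) rep(0, nrow(tab)) else {
    # hint refers to the primer 5' sense coordinate: ref_start on the sense
    # strand, ref_end on the antisense strand
    five <- ifelse(tab$strand == "sense", tab$ref_start, tab$ref_end)
    abs(five - ref_hint)
  }
  ord <- order(tab$mm, hint_dist, tab$ref_start,
               match(tab$strand, c("sense", "antisense")))
  best <- tab[ord[1], ]
  list(template_id = tid, strand = best$strand,
       ref_start = as.integer(best$ref_start),
       ref_end = as.integer(best$ref_end),
       covered = best$covered, mismatches = as.integer(best$mm))
}
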