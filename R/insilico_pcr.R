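# Mismatch-tolerant in-silico PCR: binding profiles, amplification calls
# under a Primer-BLAST-style rejection rule, panel screening, and
# fixed-width mismatch-alignment reports.
#
# Rejection rule: a template is called NON_TARGET when either primer shows
# at least `reject_total` total mismatches including at least
# `reject_window` within the 3'-terminal window (default 5 nt, the
# convention of common specificity-screening tools). Amplification needs
# both primers to extend, so the rule is applied per primer.

#' Screening thresholds
#'
#' @param window_nt width of the 3'-terminal window, nt.
#' @param reject_total total-mismatch threshold of the rejection rule.
#' @param reject_window 3'-window mismatch threshold of the rejection rule.
#' @return a \code{screen_thresholds} list.
#' @export
screen_thresholds <- function(window_nt = 5L, reject_total = 4L,
                              reject_window = 2L) {
  stopifnot(window_nt >= 1, reject_total >= 1, reject_window >= 1)
  structure(list(window_nt = as.integer(window_nt),
                 reject_total = as.integer(reject_total),
                 reject_window = as.integer(reject_window)),
            class = "screen_thresholds")
}

#' Per-position binding profile of a primer on a template
#'
#' Anchors the primer (exhaustive ungapped search, both strands), then
#' classifies each primer position 5' to 3': match, mismatch, gap,
#' ambiguous (template IUPAC code that includes the primer base), or
#' missing (footprint beyond the template end). Gap and missing positions
#' count toward the mismatch total, but missing positions are excluded from
#' the 3'-window count so that truncated records cannot fabricate
#' 3'-terminal evidence. \code{template_base} is reported in the primer
#' frame (the base that would print under the primer in an alignment
#' figure); the annealing-strand doublet base is its complement.
#'
#' @param primer \code{primer} object.
#' @param template single-row panel data.frame or sequence string.
#' @param ref_hint optional expected 5' sense coordinate (defaults to the
#'   primer's \code{ref_position}).
#' @param thresholds \code{\link{screen_thresholds}}.
#' @param weights 3'-mismatch weight table.
#' @return a \code{mismatch_profile}: anchor, positions data.frame
#'   (primer_base, template_base, status), total_mismatches,
#'   three_prime_window_mismatches, terminal_mismatch, three_prime_weight,
#'   n_ambiguous.
#' @export
profile_binding <- function(primer, template, ref_hint = NULL,
                            thresholds = screen_thresholds(),
                            weights = default_mismatch_weights()) {
  stopifnot(inherits(primer, "primer"))
  if (is.null(ref_hint)) ref_hint <- primer$ref_position
  if (is.na(ref_hint)) ref_hint <- NULL
  tseq <- if (is.data.frame(template)) template$residues else template
  if (nchar(tseq) < nchar(primer$sequence)) {
    stop("template shorter than primer", call. = FALSE)
  }
  anchor <- anchor_primer(primer, template, ref_hint = ref_hint)
  pchars <- split_chars(primer$sequence)
  plen <- length(pchars)
  tchars <- split_chars(normalize_dna(tseq, allow_gap = TRUE,
                                      what = "template"))
  tlen <- length(tchars)
  # template bases in the primer frame, 5'->3' along the primer
  tpos <- seq(anchor$ref_start, anchor$ref_end)
  raw <- rep("", plen)
  inb <- tpos >= 1L & tpos <= tlen
  raw[inb] <- tchars[tpos[inb]]
  tframe <- if (anchor$strand == "sense") raw else {
    rev(vapply(raw, function(b) if (nzchar(b)) COMPLEMENT[[b]] else "",
               character(1)))
  }
  status <- vapply(seq_len(plen), function(i) {
    tb <- tframe[i]
    if (!nzchar(tb)) return("missing")
    if (tb == "-") return("gap")
    if (!iupac_contains(tb, pchars[i])) return("mismatch")
    if (tb %in% c("A", "C", "G", "T")) "match" else "ambiguous"
  }, character(1))
  win <- seq(max(1L, plen - thresholds$window_nt + 1L), plen)
  total <- sum(status %in% c("mismatch", "gap", "missing"))
  window_mm <- sum(status[win] %in% c("mismatch", "gap"))
  terminal <- status[plen] %in% c("mismatch", "gap")
  # max inhibition weight among 3'-window substitution mismatches,
  # doublet = (primer base, complement of the primer-frame template base)
  wvals <- vapply(win, function(i) {
    if (status[i] != "mismatch") return(NA_real_)
    tb <- tframe[i]
    if (!tb %in% c("A", "C", "G", "T")) return(NA_real_)
    weights[pchars[i], COMPLEMENT[[tb]]]
  }, numeric(1))
  structure(list(
    primer_name = primer$name,
    anchor = anchor,
    positions = data.frame(primer_base = pchars, template_base = tframe,
                           status = status, stringsAsFactors = FALSE),
    total_mismatches = total,
    three_prime_window_mismatches = window_mm,
    terminal_mismatch = terminal,
    three_prime_weight = if (all(is.na(wvals))) 0 else max(wvals,
                                                           na.rm = TRUE),
    n_ambiguous = sum(status == "ambiguous")),
    class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat(sprintf("%s: %d total mismatches (%d in 3' window%s), strand %s\n",
              x$primer_name, x$total_mismatches,
              x$three_prime_window_mismatches,
              ifelse(x$terminal_mismatch, ", terminal", ""),
              x$anchor$strand))
  invisible(x)
}

#' Predict amplification of a template by a primer pair
#'
#' Categories: \code{NON_TARGET} when either primer trips the rejection rule
#' (total >= reject_total AND 3'-window >= reject_window) or the two anchors
#' are orientation-inconsistent; otherwise \code{UNLIKELY} when any
#' 3'-window mismatch is present on either primer (3'-terminal mismatches
#' drive false negatives); otherwise \code{PROBABLE} when any mismatch or
#' ambiguity remains outside the window; \code{PERFECT} only with zero
#' mismatches and zero ambiguities on both footprints. The product length
#' uses the inclusive 5'-to-5' convention.
#'
#' @param pair \code{primer_pair}.
#' @param template single-row panel data.frame or sequence string.
#' @param thresholds \code{\link{screen_thresholds}}.
#' @return an \code{amplification_call}: category, product_length (NA for
#'   NON_TARGET), forward_profile, reverse_profile.
#' @export
call_amplification <- function(pair, template,
                               thresholds = screen_thresholds()) {
  stopifnot(inherits(pair, "primer_pair"))
  fp <- profile_binding(pair$forward, template, thresholds = thresholds)
  rp <- profile_binding(pair$reverse, template, thresholds = thresholds)
  fa <- fp$anchor; ra <- rp$anchor
  consistent <- FALSE
  product <- NA_integer_
  if (fa$strand == "sense" && ra$strand == "antisense" &&
      fa$ref_start < ra$ref_end) {
    consistent <- TRUE
    product <- ra$ref_end - fa$ref_start + 1L
  } else if (fa$strand == "antisense" && ra$strand == "sense" &&
             ra$ref_start < fa$ref_end) {
    # template supplied as the reverse-complement strand
    consistent <- TRUE
    product <- fa$ref_end - ra$ref_start + 1L
  }
  rejected <- function(p) {
    p$total_mismatches >= thresholds$reject_total &&
      p$three_prime_window_mismatches >= thresholds$reject_window
  }
  category <- if (!consistent || rejected(fp) || rejected(rp)) {
    "NON_TARGET"
  } else if (fp$three_prime_window_mismatches > 0 ||
             rp$three_prime_window_mismatches > 0) {
    "UNLIKELY"
  } else if (fp$total_mismatches > 0 || rp$total_mismatches > 0 ||
             fp$n_ambiguous > 0 || rp$n_ambiguous > 0) {
    "PROBABLE"
  } else {
    "PERFECT"
  }
  if (category == "NON_TARGET") product <- NA_integer_
  structure(list(category = category, product_length = product,
                 forward_profile = fp, reverse_profile = rp),
            class = "amplification_call")
}

#' @export
print.amplification_call <- function(x, ...) {
  cat(sprintf("%s (product %s bp)\n", x$category,
              ifelse(is.na(x$product_length), "-", x$product_length)))
  print(x$forward_profile); print(x$reverse_profile)
  invisible(x)
}

#' Screen a panel of templates against a primer pair
#'
#' Calls every template (none is dropped: an unanchorable or truncated
#' record surfaces with its covered fraction) and groups deduplicated
#' mismatch patterns per species, the form in which specificity figures
#' display one row per distinct binding-site pattern.
#'
#' @param pair \code{primer_pair}.
#' @param panel panel data.frame (species column used for grouping when
#'   present).
#' @param thresholds \code{\link{screen_thresholds}}.
#' @return a \code{specificity_report}: calls (one row per template: id,
#'   species, category, fwd/rev totals and window counts, combined_total,
#'   product_length, fwd/rev covered), patterns (species, pattern id,
#'   n_templates, combined_total, display strings), pair, thresholds,
#'   profiles (per-template list).
#' @export
screen_panel <- function(pair, panel, thresholds = screen_thresholds()) {
  stopifnot(nrow(panel) >= 1L)
  species <- if ("species" %in% names(panel)) panel$species else
    rep(NA_character_, nrow(panel))
  calls <- vector("list", nrow(panel))
  profiles <- vector("list", nrow(panel))
  for (i in seq_len(nrow(panel))) {
    cl <- call_amplification(pair, panel[i, , drop = FALSE], thresholds)
    profiles[[i]] <- cl
    fp <- cl$forward_profile; rp <- cl$reverse_profile
    calls[[i]] <- data.frame(
      id = panel$id[i],
      species = species[i],
      category = cl$category,
      fwd_total = fp$total_mismatches,
      rev_total = rp$total_mismatches,
      fwd_window = fp$three_prime_window_mismatches,
      rev_window = rp$three_prime_window_mismatches,
      combined_total = fp$total_mismatches + rp$total_mismatches,
      product_length = cl$product_length,
      fwd_covered = fp$anchor$covered,
      rev_covered = rp$anchor$covered,
      stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, calls)
  names(profiles) <- panel$id
  patterns <- pattern_groups(profiles, species)
  structure(list(calls = calls, patterns = patterns, pair = pair,
                 thresholds = thresholds, profiles = profiles),
            class = "specificity_report")
}

# Deduplicate per-species mismatch patterns across both footprints.
pattern_groups <- function(profiles, species) {
  disp <- vapply(profiles, function(cl) {
    paste(profile_display(cl$forward_profile),
          profile_display(cl$reverse_profile), sep = "|")
  }, character(1))
  combined <- vapply(profiles, function(cl) {
    cl$forward_profile$total_mismatches +
      cl$reverse_profile$total_mismatches
  }, numeric(1))
  key <- paste(species, disp, sep = "\r")
  groups <- split(seq_along(profiles), key)
  rows <- lapply(groups, function(idx) {
    data.frame(species = species[idx[1]],
               pattern = disp[idx[1]],
               n_templates = length(idx),
               member_ids = paste(names(profiles)[idx], collapse = ","),
               combined_total = combined[idx[1]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$species, out$combined_total, out$pattern), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# One display string per profile: '.' match, template letter for a
# mismatch, lowercase letter for an ambiguous position, '-' gap, '~'
# missing data.
profile_display <- function(p) {
  st <- p$positions$status
  tb <- p$positions$template_base
  chars <- ifelse(st == "match", ".",
           ifelse(st == "mismatch", tb,
           ifelse(st == "ambiguous", tolower(tb),
           ifelse(st == "gap", "-", "~"))))
  paste(chars, collapse = "")
}

#' Render a fixed-width mismatch-alignment report
#'
#' Text in the style of published primer-specificity figures: the primer
#' sequence as header, one dotted row per deduplicated pattern with its
#' mismatch count in a right-hand column, and an asterisk row marking
#' columns conserved across all patterns.
#'
#' @param report \code{specificity_report}.
#' @return a single character string (embedded newlines).
#' @export
render_mismatch_alignment <- function(report) {
  stopifnot(inherits(report, "specificity_report"))
  pats <- report$patterns
  if (nrow(pats) == 0L) stop("empty report", call. = FALSE)
  halves <- strsplit(pats$pattern, "|", fixed = TRUE)
  render_half <- function(side, prm) {
    rows <- vapply(halves, `[[`, character(1), side)
    counts <- vapply(seq_len(nrow(pats)), function(i) {
      sum(split_chars(rows[i]) != ".")
    }, numeric(1))
    label <- sprintf("%s (%s)", prm$name, prm$orientation)
    width <- max(nchar(label),
                 nchar(paste(pats$species, pats$member_ids)), na.rm = TRUE)
    mat <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    conserved <- apply(mat, 2, function(col) all(col == "."))
    lines <- c(
      sprintf("%-*s  %s", width, "", paste(ifelse(conserved, "*", " "),
                                           collapse = "")),
      sprintf("%-*s  %s  mismatches", width, label, prm$sequence),
      vapply(seq_len(nrow(pats)), function(i) {
        sprintf("%-*s  %s  %d", width,
                paste(pats$species[i], pats$member_ids[i]), rows[i],
                counts[i])
      }, character(1)))
    paste(lines, collapse = "\n")
  }
  paste(render_half(1, report$pair$forward),
        render_half(2, report$pair$reverse),
        sep = "\n\n")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat(sprintf("specificity_report: %d templates, %d pattern groups\n",
              nrow(x$calls), nrow(x$patterns)))
  print(utils::head(x$calls, 10))
  invisible(x)
}
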