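# Species-specific primer candidates and pair ranking.
#
# The design principle: put the primer 3' terminus on a diagnostic site (a
# column where all target sequences share one base that every confounder
# differs from), and prefer sites where the resulting 3'-terminal
# primer/template doublet is of a strongly extension-inhibiting type. The
# doublet notation "X/Y" is (primer 3' base, template base read 3'->5'
# opposite it), i.e. the base on the strand the primer anneals to. G/A and
# C/C doublets inhibit Taq extension most strongly; T/C, T/G, T/T, G/G and
# C/A are intermediate; remaining non-complementary doublets are weakest.

#' Default 3'-mismatch inhibition weight table
#'
#' A 4x4 matrix, rows = primer 3' base, columns = template base (annealing
#' strand). Watson-Crick matches are 0. G/A and C/C carry the maximum weight
#' (1.0); T/C, T/G, T/T, G/G, C/A carry 0.6; the remaining non-complementary
#' doublets 0.3. The ordering encodes relative extension-inhibition
#' strength; the magnitudes are tunable knobs, not measurements.
#'
#' @return numeric 4x4 matrix with dimnames (primer, template).
#' @export
default_mismatch_weights <- function() {
  b <- c("A", "C", "G", "T")
  w <- matrix(0.3, 4, 4, dimnames = list(primer = b, template = b))
  w["A", "T"] <- 0; w["T", "A"] <- 0; w["G", "C"] <- 0; w["C", "G"] <- 0
  w["G", "A"] <- 1.0; w["C", "C"] <- 1.0
  for (d in list(c("T", "C"), c("T", "G"), c("T", "T"),
                 c("G", "G"), c("C", "A"))) {
    w[d[1], d[2]] <- 0.6
  }
  w
}

check_weight_table <- function(w) {
  b <- c("A", "C", "G", "T")
  stopifnot(is.matrix(w), identical(dim(w), c(4L, 4L)))
  if (!identical(rownames(w), b) || !identical(colnames(w), b)) {
    stop("weight table must have A,C,G,T dimnames", call. = FALSE)
  }
  comp <- COMPLEMENT[b]
  for (p in b) {
    if (w[p, comp[p]] != 0) {
      stop("weight of a Watson-Crick match must be 0", call. = FALSE)
    }
  }
  if (any(w < 0 | w > 1)) stop("weights must lie in [0,1]", call. = FALSE)
  invisible(w)
}

#' 3'-terminal mismatch inhibition weight
#'
#' @param primer_base primer 3' base (unambiguous).
#' @param template_base base on the annealing template strand opposite it.
#' @param table weight table (\code{\link{default_mismatch_weights}}).
#' @return 0 for a Watson-Crick match, otherwise the table weight.
#' @examples
#' mismatch_weight("A", "T") # 0, complementary
#' mismatch_weight("G", "A") # 1, strongest inhibition
#' @export
mismatch_weight <- function(primer_base, template_base,
                            table = default_mismatch_weights()) {
  b <- c("A", "C", "G", "T")
  if (!primer_base %in% b || !template_base %in% b) {
    stop("mismatch_weight requires unambiguous A/C/G/T bases", call. = FALSE)
  }
  check_weight_table(table)
  table[primer_base, template_base]
}

#' Construct an oriented primer
#'
#' @param name primer name.
#' @param sequence 5'-to-3' unambiguous DNA, 15-40 nt.
#' @param orientation "forward" or "reverse".
#' @param ref_position sense-strand coordinate of the primer's 5' end on the
#'   reference (for a reverse primer this is the larger coordinate of its
#'   footprint, matching the convention that names a reverse primer after
#'   its 5' position).
#' @return a \code{primer} object.
#' @export
primer <- function(name, sequence, orientation = c("forward", "reverse"),
                   ref_position = NA_integer_) {
  orientation <- match.arg(orientation)
  sequence <- check_unambiguous(sequence, what = paste0("primer ", name))
  n <- nchar(sequence)
  if (n < 15 || n > 40) {
    stop("primer length ", n, " outside 15-40 nt", call. = FALSE)
  }
  structure(list(name = name, sequence = sequence,
                 orientation = orientation,
                 ref_position = as.integer(ref_position)),
            class = "primer")
}

#' @export
print.primer <- function(x, ...) {
  cat(sprintf("%s (%s) 5'-%s-3' [%d nt, 5' at ref %s]\n", x$name,
              x$orientation, x$sequence, nchar(x$sequence),
              ifelse(is.na(x$ref_position), "?", x$ref_position)))
  invisible(x)
}

#' Pair a forward and a reverse primer
#'
#' The theoretical product length uses the inclusive 5'-to-5' convention on
#' reference coordinates: reverse 5' position - forward 5' position + 1.
#'
#' @param forward,reverse \code{primer} objects of matching orientation.
#' @return a \code{primer_pair} object.
#' @export
primer_pair <- function(forward, reverse) {
  stopifnot(inherits(forward, "primer"), inherits(reverse, "primer"))
  if (forward$orientation != "forward" || reverse$orientation != "reverse") {
    stop("primer_pair requires a forward and a reverse primer",
         call. = FALSE)
  }
  len <- NA_integer_
  if (!is.na(forward$ref_position) && !is.na(reverse$ref_position)) {
    if (forward$ref_position >= reverse$ref_position) {
      stop("forward 5' coordinate must precede the reverse 5' coordinate",
           call. = FALSE)
    }
    len <- reverse$ref_position - forward$ref_position + 1L
  }
  structure(list(forward = forward, reverse = reverse,
                 theoretical_product_length = len),
            class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  print(x$forward); print(x$reverse)
  cat(sprintf("theoretical product: %s bp\n",
              ifelse(is.na(x$theoretical_product_length), "?",
                     x$theoretical_product_length)))
  invisible(x)
}

#' The published Trissolcus japonicus diagnostic primer pair
#'
#' TJ234F/TJ460R, species-specific CO1 primers for the samurai wasp
#' (an egg parasitoid of the brown marmorated stink bug). The names encode
#' the sense-strand 5' coordinates 234 and 460 on the partial CO1 barcode,
#' giving a theoretical 227-bp amplicon.
#'
#' @return a \code{primer_pair}.
#' @examples
#' tj_primer_pair()
#' @export
tj_primer_pair <- function() {
  primer_pair(
    primer("TJ234F", "ATCCCATCATTAATTTTATTAATCTATAGG", "forward", 234L),
    primer("TJ460R", "CATGTAAATAACGTTCAATTATTAATTGATA", "reverse", 460L))
}

#' Design constraints for candidate enumeration and pairing
#'
#' Defaults form an envelope around typical diagnostic assays on AT-rich
#' barcodes: 18-34 nt primers, NN Tm 48-62 degC (under the package's
#' 50 mM Na+, 0.25 uM conditions the published 30/31-nt AT-rich diagnostic
#' primers estimate near 50 degC, and bench annealing gradients for such
#' assays span 48-60 degC), pair delta-Tm <= 5 degC, 100-500 nt amplicons,
#' 3' terminus required on a diagnostic site.
#'
#' @param length_range c(min, max) primer length, nt.
#' @param tm_range c(min, max) Tm window, degC.
#' @param max_dtm maximum |Tm difference| within a pair, degC.
#' @param amplicon_range c(min, max) product length, nt.
#' @param require_three_prime_site keep the 3' terminus on a diagnostic site.
#' @param weights 3'-mismatch weight table.
#' @param thermo \code{\link{thermo_conditions}} used for Tm.
#' @return a \code{design_constraints} list.
#' @export
design_constraints <- function(length_range = c(18L, 34L),
                               tm_range = c(48, 62),
                               max_dtm = 5,
                               amplicon_range = c(100L, 500L),
                               require_three_prime_site = TRUE,
                               weights = default_mismatch_weights(),
                               thermo = thermo_conditions()) {
  stopifnot(length_range[1] <= length_range[2],
            tm_range[1] <= tm_range[2],
            amplicon_range[1] <= amplicon_range[2])
  check_weight_table(weights)
  structure(list(length_range = as.integer(length_range),
                 tm_range = tm_range, max_dtm = max_dtm,
                 amplicon_range = as.integer(amplicon_range),
                 require_three_prime_site = require_three_prime_site,
                 weights = weights, thermo = thermo),
            class = "design_constraints")
}

# 3' doublet weights of a candidate against each non-target row.
# site_base_nontarget: sense-strand bases of the non-target rows at the
# diagnostic column. The annealing-strand base opposite the primer 3' is the
# complement of the sense base for a forward primer, the sense base itself
# for a reverse primer.
nontarget_three_prime_weights <- function(p3_base, nontarget_sense,
                                          orientation, weights) {
  tmpl <- if (orientation == "forward") {
    vapply(nontarget_sense, function(b) {
      if (b %in% c("A", "C", "G", "T")) COMPLEMENT[[b]] else NA_character_
    }, character(1))
  } else {
    ifelse(nontarget_sense %in% c("A", "C", "G", "T"), nontarget_sense,
           NA_character_)
  }
  vapply(tmpl, function(tb) {
    if (is.na(tb)) return(NA_real_)
    weights[p3_base, tb]
  }, numeric(1))
}

#' Enumerate species-specific primer candidates
#'
#' For every diagnostic site and both orientations, grows a primer with its
#' 3' terminus on the site, extending 5'-ward from the minimum length until
#' the Tm enters the constraint window (diagnostic regions are often
#' AT-rich, so candidates tend to come out long). The target-consensus
#' sense sequence provides the primer residues; columns under the footprint
#' must be fixed and unambiguous in the targets.
#'
#' @param aln \code{barcode_alignment}.
#' @param target_ids,nontarget_ids disjoint id sets.
#' @param constraints \code{\link{design_constraints}}.
#' @return data.frame of candidates: name, sequence, orientation,
#'   ref_position (5' sense coordinate), site_pos (3' terminus = diagnostic
#'   site), length, tm, min_nontarget_weight, mean_nontarget_weight,
#'   doublets (comma-separated per non-target "X/Y" doublets). Empty (with a
#'   "diagnostics" attribute) when nothing satisfies the constraints.
#' @export
enumerate_candidates <- function(aln, target_ids, nontarget_ids,
                                 constraints = design_constraints()) {
  stopifnot(inherits(aln, "barcode_alignment"),
            inherits(constraints, "design_constraints"))
  sites <- diagnostic_sites(aln, target_ids, nontarget_ids)
  empty <- data.frame(name = character(), sequence = character(),
                      orientation = character(), ref_position = integer(),
                      site_pos = integer(), length = integer(),
                      tm = numeric(), min_nontarget_weight = numeric(),
                      mean_nontarget_weight = numeric(),
                      doublets = character(), stringsAsFactors = FALSE)
  if (nrow(sites) == 0L) {
    attr(empty, "diagnostics") <- "no diagnostic sites in the alignment"
    return(empty)
  }
  tmat <- aln$mat[target_ids, , drop = FALSE]
  nmat <- aln$mat[nontarget_ids, , drop = FALSE]
  # target consensus where fixed and unambiguous, NA elsewhere
  cons <- apply(tmat, 2, function(col) {
    u <- unique(col)
    if (length(u) == 1L && u %in% c("A", "C", "G", "T")) u else NA_character_
  })
  lmin <- constraints$length_range[1]; lmax <- constraints$length_range[2]
  notes <- character()
  rows <- list()
  for (k in seq_len(nrow(sites))) {
    pos <- sites$ref_pos[k]
    for (orientation in c("forward", "reverse")) {
      found <- NULL
      for (len in seq(lmin, lmax)) {
        span <- if (orientation == "forward") {
          seq(pos - len + 1L, pos)
        } else {
          seq(pos, pos + len - 1L)
        }
        if (span[1] < 1L || span[length(span)] > aln$ncol) next
        bases <- cons[span]
        if (anyNA(bases)) next
        sense <- paste(bases, collapse = "")
        pseq <- if (orientation == "forward") sense else
          reverse_complement(sense)
        tm <- tryCatch(
          melting_temperature(pseq, constraints$thermo),
          error = function(e) NA_real_)
        if (is.na(tm)) next
        if (tm < constraints$tm_range[1]) next  # extend further 5'-ward
        if (tm > constraints$tm_range[2]) break # overshot; longer only warms
        p3 <- substr(pseq, len, len)
        w <- nontarget_three_prime_weights(p3, nmat[, pos], orientation,
                                           constraints$weights)
        tmpl_bases <- if (orientation == "forward") {
          vapply(nmat[, pos], function(b)
            if (b %in% c("A","C","G","T")) COMPLEMENT[[b]] else "?",
            character(1))
        } else ifelse(nmat[, pos] %in% c("A","C","G","T"),
                      nmat[, pos], "?")
        doublets <- paste(sprintf("%s:%s/%s", nontarget_ids, p3,
                                  tmpl_bases), collapse = ",")
        found <- data.frame(
          name = sprintf("cand_%d%s", pos,
                         ifelse(orientation == "forward", "F", "R")),
          sequence = pseq, orientation = orientation,
          ref_position = if (orientation == "forward") span[1] else
            span[length(span)],
          site_pos = pos, length = len, tm = tm,
          min_nontarget_weight = min(w, na.rm = TRUE),
          mean_nontarget_weight = mean(w, na.rm = TRUE),
          doublets = doublets, stringsAsFactors = FALSE)
        break
      }
      if (is.null(found)) {
        notes <- c(notes, sprintf(
          "site %d (%s): no length in [%d,%d] reaches Tm window [%g,%g]",
          pos, orientation, lmin, lmax,
          constraints$tm_range[1], constraints$tm_range[2]))
      } else {
        rows[[length(rows) + 1L]] <- found
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else empty
  attr(out, "diagnostics") <- if (length(notes)) notes else "ok"
  out
}

#' Rank forward x reverse candidate combinations into pairs
#'
#' Keeps combinations whose theoretical product length falls in the amplicon
#' window and whose Tm difference is within \code{max_dtm}, then ranks by
#' (descending sum of per-non-target minimum 3' weights across the two
#' primers, ascending |dTm|, ascending product length, forward position,
#' reverse position). The order is a deterministic total order, invariant to
#' the input order of candidates.
#'
#' @param candidates data.frame from \code{\link{enumerate_candidates}}.
#' @param constraints \code{\link{design_constraints}}.
#' @return data.frame of ranked pairs with forward/reverse sequences,
#'   coordinates, product_length, dtm, specificity_score; zero rows if no
#'   combination qualifies.
#' @export
design_pairs <- function(candidates, constraints = design_constraints()) {
  fwd <- candidates[candidates$orientation == "forward", , drop = FALSE]
  rev <- candidates[candidates$orientation == "reverse", , drop = FALSE]
  empty <- data.frame(forward_name = character(), reverse_name = character(),
                      forward_seq = character(), reverse_seq = character(),
                      forward_pos = integer(), reverse_pos = integer(),
                      product_length = integer(), dtm = numeric(),
                      specificity_score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(fwd) == 0L || nrow(rev) == 0L) return(empty)
  grid <- expand.grid(i = seq_len(nrow(fwd)), j = seq_len(nrow(rev)))
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    f <- fwd[grid$i[k], ]; r <- rev[grid$j[k], ]
    if (f$ref_position >= r$ref_position) return(NULL)
    plen <- r$ref_position - f$ref_position + 1L
    if (plen < constraints$amplicon_range[1] ||
        plen > constraints$amplicon_range[2]) return(NULL)
    dtm <- abs(f$tm - r$tm)
    if (dtm > constraints$max_dtm) return(NULL)
    # per non-target, the pair is only as discriminating as its weaker
    # primer terminus: score = sum over non-targets of min(fwd_w, rev_w)
    fw <- parse_doublet_weights(f, constraints$weights)
    rw <- parse_doublet_weights(r, constraints$weights)
    score <- sum(pmin(fw, rw), na.rm = TRUE)
    data.frame(forward_name = f$name, reverse_name = r$name,
               forward_seq = f$sequence, reverse_seq = r$sequence,
               forward_pos = f$ref_position, reverse_pos = r$ref_position,
               product_length = plen, dtm = dtm,
               specificity_score = score, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) return(empty)
  out <- out[order(-out$specificity_score, out$dtm, out$product_length,
                   out$forward_pos, out$reverse_pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Recover per-non-target weights from a candidate row's doublet string.
parse_doublet_weights <- function(cand, weights) {
  parts <- strsplit(cand$doublets, ",", fixed = TRUE)[[1]]
  vapply(parts, function(p) {
    d <- sub("^[^:]*:", "", p)
    pb <- substr(d, 1, 1); tb <- substr(d, 3, 3)
    if (!tb %in% c("A", "C", "G", "T")) return(NA_real_)
    weights[pb, tb]
  }, numeric(1), USE.NAMES = FALSE)
}
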