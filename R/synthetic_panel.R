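# Synthetic barcode panels with planted, fully known structure.
#
# The generator emulates the kind of panel a diagnostic-PCR design starts
# from: an AT-rich ~650-nt barcode reference, a target species carrying a
# few haplotypes that differ at a handful of sites, and confounder species
# at a configurable divergence, with diagnostic sites planted inside
# candidate primer windows. Every random draw is governed by one explicit
# seed, and the truth (planted sites, haplotype memberships, expected
# amplification calls) is emitted alongside the sequences so that every
# other module can be tested against it without downloads.

#' Specification of a synthetic barcode panel
#'
#' Defaults emulate a design panel for an AT-rich CO1 barcode: a 658-nt
#' reference at GC 0.25, three target haplotypes (sizes 5/3/2) differing at
#' two or three internal sites, and eight confounder species (two records
#' each) at 0.10 substitutions/site, with two diagnostic sites planted so
#' that a forward primer ending on the first yields a G/A doublet and a
#' reverse primer ending on the second a C/C doublet against every
#' confounder.
#'
#' @param ref_length reference length, nt.
#' @param gc GC fraction of the random background (AT-rich default 0.25).
#' @param hap_sizes integer vector: number of records per target haplotype;
#'   the first haplotype is the reference sequence itself.
#' @param hap_variant_sites list (one element per additional haplotype) of
#'   reference positions where that haplotype differs from the reference.
#' @param n_confounder_species,confounder_n number of confounder species
#'   and records per species.
#' @param divergence per-site substitution probability of each confounder
#'   species from the reference, in [0, 0.5].
#' @param within_species_div extra per-site substitution probability of
#'   each confounder individual beyond the first, creating the multiple
#'   per-species mismatch patterns seen in real panels.
#' @param planted_sites data.frame(position, target_base, confounder_base):
#'   diagnostic sites forced into every sequence.
#' @param target_species,target_countries labels for the target records
#'   (countries recycled across records).
#' @param confounder_country label for confounder records.
#' @param seed integer seed governing all randomness.
#' @return a \code{panel_spec} list.
#' @export
panel_spec <- function(ref_length = 658L,
                       gc = 0.25,
                       hap_sizes = c(5L, 3L, 2L),
                       hap_variant_sites = list(c(300L, 350L),
                                                c(310L, 360L, 365L)),
                       n_confounder_species = 8L,
                       confounder_n = 2L,
                       divergence = 0.10,
                       within_species_div = 0.002,
                       planted_sites = data.frame(
                         position = c(263L, 430L),
                         target_base = c("G", "G"),
                         confounder_base = c("T", "C"),
                         stringsAsFactors = FALSE),
                       target_species = "target_sp",
                       target_countries = c("USA", "Canada", "Switzerland",
                                            "Italy", "China", "Japan"),
                       confounder_country = "USA",
                       seed = 20210518L) {
  if (divergence < 0 || divergence > 0.5) {
    stop("divergence must lie in [0, 0.5]", call. = FALSE)
  }
  if (length(hap_sizes) > 1L &&
      length(hap_variant_sites) != length(hap_sizes) - 1L) {
    stop("need one variant-site set per haplotype beyond the first",
         call. = FALSE)
  }
  pos <- c(planted_sites$position, unlist(hap_variant_sites))
  if (anyDuplicated(planted_sites$position)) {
    stop("planted positions must be distinct", call. = FALSE)
  }
  if (length(pos) && (min(pos) < 1L || max(pos) > ref_length)) {
    stop("planted/variant positions outside the reference", call. = FALSE)
  }
  structure(list(ref_length = as.integer(ref_length), gc = gc,
                 hap_sizes = as.integer(hap_sizes),
                 hap_variant_sites = lapply(hap_variant_sites, as.integer),
                 n_confounder_species = as.integer(n_confounder_species),
                 confounder_n = as.integer(confounder_n),
                 divergence = divergence,
                 within_species_div = within_species_div,
                 planted_sites = planted_sites,
                 target_species = target_species,
                 target_countries = target_countries,
                 confounder_country = confounder_country,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

region_of_country <- function(country) {
  map <- c(USA = "North America", Canada = "North America",
           Switzerland = "Europe", Italy = "Europe",
           China = "Asia", Japan = "Asia", `South Korea` = "Asia")
  out <- unname(map[country])
  ifelse(is.na(out), "unknown", out)
}

random_base <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

mutate_sites <- function(chars, idx) {
  for (i in idx) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  chars
}

#' Simulate a barcode panel with known truth
#'
#' Deterministic for a fixed seed. Confounder backbones are drawn by
#' uniform random substitution (Jukes-Cantor-like, no indels) at the
#' specified divergence, except at planted diagnostic sites, which are
#' forced; target haplotypes share the planted target bases and differ from
#' the reference only at their declared variant sites.
#'
#' @param spec \code{\link{panel_spec}}.
#' @param seed optional override of \code{spec$seed}.
#' @return a \code{panel_truth} list: panel (data.frame with metadata
#'   columns), metadata, reference (the haplotype-1 sequence), planted
#'   sites, hap_membership (data.frame id, hap), spec.
#' @export
simulate_panel <- function(spec = panel_spec(), seed = NULL) {
  stopifnot(inherits(spec, "panel_spec"))
  if (!is.null(seed)) spec$seed <- as.integer(seed)
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$seed)

  L <- spec$ref_length
  ref <- random_base(L, spec$gc)
  ps <- spec$planted_sites
  ref[ps$position] <- ps$target_base

  # target haplotype sequences
  hap_seqs <- list(ref)
  if (length(spec$hap_sizes) > 1L) {
    for (h in seq_along(spec$hap_variant_sites)) {
      hap_seqs[[h + 1L]] <- mutate_sites(ref, spec$hap_variant_sites[[h]])
    }
  }

  ids <- character(); residues <- character(); species <- character()
  country <- character(); hap_of <- integer()
  ti <- 0L
  for (h in seq_along(spec$hap_sizes)) {
    for (i in seq_len(spec$hap_sizes[h])) {
      ti <- ti + 1L
      ids <- c(ids, sprintf("TGT%03d", ti))
      residues <- c(residues, paste(hap_seqs[[h]], collapse = ""))
      species <- c(species, spec$target_species)
      country <- c(country,
                   spec$target_countries[(ti - 1L) %%
                                           length(spec$target_countries) + 1L])
      hap_of <- c(hap_of, h)
    }
  }
  free <- setdiff(seq_len(L), ps$position)
  for (sp in seq_len(spec$n_confounder_species)) {
    backbone <- ref
    mut <- free[stats::runif(length(free)) < spec$divergence]
    backbone <- mutate_sites(backbone, mut)
    backbone[ps$position] <- ps$confounder_base
    for (i in seq_len(spec$confounder_n)) {
      indiv <- backbone
      if (i > 1L && spec$within_species_div > 0) {
        extra <- free[stats::runif(length(free)) < spec$within_species_div]
        indiv <- mutate_sites(indiv, extra)
        indiv[ps$position] <- ps$confounder_base
      }
      ids <- c(ids, sprintf("CF%02d_%02d", sp, i))
      residues <- c(residues, paste(indiv, collapse = ""))
      species <- c(species, sprintf("confounder_sp%02d", sp))
      country <- c(country, spec$confounder_country)
      hap_of <- c(hap_of, NA_integer_)
    }
  }
  panel <- seq_panel(ids, residues, species = species, country = country,
                     region_group = region_of_country(country))
  metadata <- panel[, c("id", "species", "country", "region_group")]
  structure(list(panel = panel, metadata = metadata,
                 reference = paste(ref, collapse = ""),
                 planted_sites = ps,
                 hap_membership = data.frame(id = ids, hap = hap_of,
                                             stringsAsFactors = FALSE),
                 spec = spec),
            class = "panel_truth")
}

#' @export
print.panel_truth <- function(x, ...) {
  cat(sprintf(
    "panel_truth: %d records (%d target, %d confounder), ref %d nt\n",
    nrow(x$panel), sum(!is.na(x$hap_membership$hap)),
    sum(is.na(x$hap_membership$hap)), nchar(x$reference)))
  invisible(x)
}

#' Expected amplification calls from generative truth
#'
#' Computes, for a designated primer pair, the category every simulated
#' record must receive — by direct character comparison at the known
#' footprint coordinates, independent of the binding-site search used by
#' the screening code. Valid for full-length simulated records (no indels,
#' no truncation).
#'
#' @param truth \code{panel_truth}.
#' @param pair \code{primer_pair} with reference coordinates set.
#' @param thresholds \code{\link{screen_thresholds}}.
#' @return data.frame: id, category, fwd_total, rev_total, fwd_window,
#'   rev_window, product_length.
#' @export
panel_truth_calls <- function(truth, pair,
                              thresholds = screen_thresholds()) {
  stopifnot(inherits(truth, "panel_truth"), inherits(pair, "primer_pair"))
  f <- pair$forward; r <- pair$reverse
  flen <- nchar(f$sequence); rlen <- nchar(r$sequence)
  fpos <- f$ref_position                  # sense 5' of forward footprint
  rpos <- r$ref_position                  # sense 5' (largest coordinate)
  fchars <- split_chars(f$sequence)
  # reverse primer in sense-strand frame
  rsense <- split_chars(reverse_complement(r$sequence))
  w <- thresholds$window_nt
  rows <- lapply(seq_len(nrow(truth$panel)), function(i) {
    t <- split_chars(truth$panel$residues[i])
    fwin <- t[seq(fpos, fpos + flen - 1L)]
    fmm <- fchars != fwin
    rwin <- t[seq(rpos - rlen + 1L, rpos)]
    rmm <- rsense != rwin
    # forward primer 3' end is the rightmost sense position; reverse primer
    # 3' end is the leftmost sense position of its footprint
    f_window <- sum(fmm[seq(flen - w + 1L, flen)])
    r_window <- sum(rmm[seq_len(w)])
    ft <- sum(fmm); rt <- sum(rmm)
    cat_ <- if ((ft >= thresholds$reject_total &&
                 f_window >= thresholds$reject_window) ||
                (rt >= thresholds$reject_total &&
                 r_window >= thresholds$reject_window)) {
      "NON_TARGET"
    } else if (f_window > 0 || r_window > 0) {
      "UNLIKELY"
    } else if (ft > 0 || rt > 0) {
      "PROBABLE"
    } else "PERFECT"
    data.frame(id = truth$panel$id[i], category = cat_,
               fwd_total = ft, rev_total = rt,
               fwd_window = f_window, rev_window = r_window,
               product_length = if (cat_ == "NON_TARGET") NA_integer_ else
                 rpos - fpos + 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write a simulated panel to disk
#'
#' Emits FASTA, metadata TSV, a planted-sites TSV and a truth JSON next to
#' each other, the layout the command-line \code{simulate} subcommand uses.
#'
#' @param truth \code{panel_truth}.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_panel <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(truth$panel, file.path(dir, "panel.fasta"))
  utils::write.table(truth$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$planted_sites,
                     file.path(dir, "planted_sites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(truth$hap_membership,
                     file.path(dir, "hap_membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste0("seed\t", truth$spec$seed),
             file.path(dir, "seed.tsv"))
  invisible(dir)
}

#' Synthetic screening reference carrying the published primer footprints
#'
#' A 658-nt synthetic barcode-like sequence with the TJ234F footprint
#' planted at sense positions 234-263 and the TJ460R footprint (reverse
#' complement) at 430-460; everything outside the footprints is simulated
#' AT-rich filler (GC 0.25, fixed internal seed). The primer binding sites
#' and the 227-bp product arithmetic are therefore exact; the remainder of
#' the sequence is NOT the real CO1 sequence of any organism.
#'
#' @return single-row panel data.frame (id "SYNREF_TJ").
#' @export
tj_synthetic_reference <- function() {
  pair <- tj_primer_pair()
  spec <- panel_spec(hap_sizes = 1L, hap_variant_sites = list(),
                     n_confounder_species = 0L,
                     planted_sites = data.frame(position = integer(),
                                                target_base = character(),
                                                confounder_base = character(),
                                                stringsAsFactors = FALSE),
                     seed = 234460L)
  truth <- simulate_panel(spec)
  chars <- split_chars(truth$reference)
  f <- pair$forward; r <- pair$reverse
  chars[seq(f$ref_position, f$ref_position + nchar(f$sequence) - 1L)] <-
    split_chars(f$sequence)
  chars[seq(r$ref_position - nchar(r$sequence) + 1L, r$ref_position)] <-
    split_chars(reverse_complement(r$sequence))
  seq_panel("SYNREF_TJ", paste(chars, collapse = ""),
            description = "synthetic barcode reference with planted TJ234F/TJ460R footprints",
            species = "target_sp (synthetic)", country = "USA",
            region_group = "North America")
}
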