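# Fixture builders and independent brute-force oracles. Oracles are written
# as plain loops over the definition being checked, deliberately sharing no
# code with the implementation paths they verify.

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

comp1 <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_plain <- function(s) {
  paste(rev(comp1[strsplit(s, "")[[1]]]), collapse = "")
}

# Exhaustive all-offsets anchoring oracle for unambiguous sequences.
# Objective: mismatches in overlap + positions off the template end;
# tie-break (mm, |5'pos - hint|, ref_start, sense-before-antisense).
oracle_anchor <- function(pseq, tseq, ref_hint = NULL, min_overlap = 10L) {
  plen <- nchar(pseq); tlen <- nchar(tseq)
  tch <- strsplit(tseq, "")[[1]]
  best <- NULL
  for (strand in c("sense", "antisense")) {
    q <- strsplit(if (strand == "sense") pseq else revcomp_plain(pseq),
                  "")[[1]]
    ov <- min(min_overlap, plen, tlen)
    for (s in seq(1L - plen + ov, tlen - ov + 1L)) {
      mm <- 0L
      for (i in seq_len(plen)) {
        tp <- s + i - 1L
        if (tp < 1L || tp > tlen || q[i] != tch[tp]) mm <- mm + 1L
      }
      five <- if (strand == "sense") s else s + plen - 1L
      key <- c(mm,
               if (is.null(ref_hint)) 0 else abs(five - ref_hint),
               s,
               if (strand == "sense") 1L else 2L)
      if (is.null(best) || lex_less(key, best$key)) {
        best <- list(key = key, strand = strand, ref_start = s,
                     ref_end = s + plen - 1L, mm = mm)
      }
    }
  }
  best
}

lex_less <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] < b[k]) return(TRUE)
    if (a[k] > b[k]) return(FALSE)
  }
  FALSE
}

# Brute-force diagnostic-column scan over a character matrix.
oracle_diag_sites <- function(mat, target_rows, nontarget_rows,
                              min_frac = 1) {
  hits <- integer()
  for (j in seq_len(ncol(mat))) {
    tb <- unique(mat[target_rows, j])
    if (length(tb) != 1L || !tb %in% c("A", "C", "G", "T")) next
    nb <- mat[nontarget_rows, j]
    if (mean(nb != tb) >= min_frac) hits <- c(hits, j)
  }
  hits
}

# Brute-force minimum spanning-tree weight: enumerate all (n-1)-edge
# subsets of the complete graph and keep the lightest connected one.
oracle_mst_weight <- function(seqs) {
  n <- length(seqs)
  if (n == 1L) return(0)
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  cmb <- utils::combn(n, 2)
  wts <- apply(cmb, 2, function(ij) ham(seqs[ij[1]], seqs[ij[2]]))
  m <- ncol(cmb)
  best <- Inf
  for (pick in utils::combn(m, n - 1L, simplify = FALSE)) {
    parent <- seq_len(n)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    comps <- n
    for (e in pick) {
      a <- find(cmb[1, e]); b <- find(cmb[2, e])
      if (a != b) { parent[a] <- b; comps <- comps - 1L }
    }
    if (comps == 1L) best <- min(best, sum(wts[pick]))
  }
  best
}

# Small aligned panel with a single planted diagnostic column.
planted_alignment <- function(n_target = 3, n_nontarget = 4, len = 40,
                              site = 20, target_base = "A",
                              nontarget_base = "G", seed = 1) {
  withr::with_seed(seed, {
    base <- random_dna(len)
    rows <- character(n_target + n_nontarget)
    for (i in seq_len(n_target)) {
      ch <- strsplit(base, "")[[1]]; ch[site] <- target_base
      rows[i] <- paste(ch, collapse = "")
    }
    for (i in seq_len(n_nontarget)) {
      ch <- strsplit(base, "")[[1]]; ch[site] <- nontarget_base
      rows[n_target + i] <- paste(ch, collapse = "")
    }
    seq_panel(c(sprintf("t%d", seq_len(n_target)),
                sprintf("n%d", seq_len(n_nontarget))), rows,
              allow_gap = TRUE)
  })
}

category_rank <- function(x) {
  match(x, c("PERFECT", "PROBABLE", "UNLIKELY", "NON_TARGET"))
}
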