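make_primer <- function(seq, orientation = "forward", pos = NA_integer_,
                        name = "p") {
  primer(name, seq, orientation, pos)
}

test_that("binding profiles count mismatches position by position", {
  withr::local_seed(14)
  tmpl <- random_dna(80)
  pseq <- substr(tmpl, 31, 50)
  p <- make_primer(pseq)
  pr <- profile_binding(p, tmpl)
  expect_equal(pr$total_mismatches, 0)
  expect_equal(pr$three_prime_window_mismatches, 0)
  expect_false(pr$terminal_mismatch)
  expect_equal(nrow(pr$positions), 20L)
  expect_true(all(pr$positions$status == "match"))

  # substitution at the 3'-terminal base
  ch <- strsplit(pseq, "")[[1]]
  ch[20] <- setdiff(c("A", "C", "G", "T"), ch[20])[1]
  pr2 <- profile_binding(make_primer(paste(ch, collapse = "")), tmpl)
  expect_equal(pr2$total_mismatches, 1)
  expect_equal(pr2$three_prime_window_mismatches, 1)
  expect_true(pr2$terminal_mismatch)

  expect_error(profile_binding(make_primer(pseq), "ACGTACGT"), "shorter")
})

test_that("profile totals equal a brute-force comparison on random pairs", {
  withr::local_seed(15)
  for (rep in 1:30) {
    tmpl <- random_dna(sample(60:120, 1))
    s <- sample(seq_len(nchar(tmpl) - 24), 1)
    core <- substr(tmpl, s, s + 23)
    ch <- strsplit(core, "")[[1]]
    k <- sample(0:4, 1)
    flip <- sample(24, k)
    for (i in flip) ch[i] <- sample(setdiff(c("A","C","G","T"), ch[i]), 1)
    pseq <- paste(ch, collapse = "")
    pr <- profile_binding(make_primer(pseq), tmpl, ref_hint = s)
    want <- sum(strsplit(pseq, "")[[1]] != strsplit(core, "")[[1]])
    expect_equal(pr$total_mismatches, want)
    expect_equal(pr$three_prime_window_mismatches, sum(flip > 19))
  }
})

test_that("reverse primers are profiled against the reverse-complemented footprint", {
  ref <- tj_synthetic_reference()
  pair <- tj_primer_pair()
  pr <- profile_binding(pair$reverse, ref)
  expect_equal(pr$anchor$strand, "antisense")
  expect_equal(pr$anchor$ref_end, 460)
  expect_equal(pr$total_mismatches, 0)
})

test_that("ambiguity under a footprint blocks PERFECT but is not a mismatch", {
  withr::local_seed(16)
  tmpl <- random_dna(100)
  f <- make_primer(substr(tmpl, 11, 30), "forward", 11L, "f")
  r <- make_primer(revcomp_plain(substr(tmpl, 61, 80)), "reverse", 80L, "r")
  pair <- primer_pair(f, r)
  expect_equal(call_amplification(pair, tmpl)$category, "PERFECT")
  ch <- strsplit(tmpl, "")[[1]]
  ch[15] <- "N"
  cl <- call_amplification(pair, paste(ch, collapse = ""))
  expect_equal(cl$category, "PROBABLE")
  expect_equal(cl$forward_profile$total_mismatches, 0)
  expect_equal(cl$forward_profile$n_ambiguous, 1)
})

test_that("amplification categories follow the rejection rule", {
  withr::local_seed(17)
  tmpl <- random_dna(300)
  f <- make_primer(substr(tmpl, 34, 63), "forward", 34L, "f")
  r <- make_primer(revcomp_plain(substr(tmpl, 230, 260)), "reverse", 260L,
                   "r")
  pair <- primer_pair(f, r)
  cl <- call_amplification(pair, tmpl)
  expect_equal(cl$category, "PERFECT")
  expect_equal(cl$product_length, 227L)

  mutate_at <- function(s, pos) {
    ch <- strsplit(s, "")[[1]]
    for (p in pos) ch[p] <- setdiff(c("A","C","G","T"), ch[p])[1]
    paste(ch, collapse = "")
  }
  # one mismatch 6 nt from the reverse 3' end: outside the 5-nt window
  # (reverse 3' end sits at sense position 230)
  cl2 <- call_amplification(pair, mutate_at(tmpl, 235))
  expect_equal(cl2$category, "PROBABLE")
  expect_equal(cl2$reverse_profile$total_mismatches, 1)
  expect_equal(cl2$reverse_profile$three_prime_window_mismatches, 0)

  # a mismatch inside the 3' window downgrades to UNLIKELY
  cl3 <- call_amplification(pair, mutate_at(tmpl, 231))
  expect_equal(cl3$category, "UNLIKELY")

  # four total with two in the forward 3' window trips the rejection rule
  cl4 <- call_amplification(pair, mutate_at(tmpl, c(36, 40, 60, 63)))
  expect_equal(cl4$forward_profile$total_mismatches, 4)
  expect_equal(cl4$forward_profile$three_prime_window_mismatches, 2)
  expect_equal(cl4$category, "NON_TARGET")
  expect_true(is.na(cl4$product_length))
})

test_that("adding mismatches never moves a call toward PERFECT", {
  withr::local_seed(18)
  for (rep in 1:10) {
    tmpl <- random_dna(250)
    f <- make_primer(substr(tmpl, 21, 44), "forward", 21L, "f")
    r <- make_primer(revcomp_plain(substr(tmpl, 181, 205)), "reverse",
                     205L, "r")
    pair <- primer_pair(f, r)
    cur <- tmpl
    prev_rank <- category_rank(call_amplification(pair, cur)$category)
    footprint <- c(21:44, 181:205)
    for (pos in sample(footprint, 6)) {  # distinct positions only
      ch <- strsplit(cur, "")[[1]]
      ch[pos] <- setdiff(c("A", "C", "G", "T"), ch[pos])[1]
      cur <- paste(ch, collapse = "")
      rank <- category_rank(call_amplification(pair, cur)$category)
      expect_gte(rank, prev_rank)
      prev_rank <- rank
    }
  }
})

test_that("panel screening reports every template and is order-invariant", {
  truth <- simulate_panel()
  pair_tab <- {
    panel <- truth$panel
    tids <- panel$id[panel$species == truth$spec$target_species]
    aln <- load_alignment(panel, tids[1])
    design_pairs(enumerate_candidates(aln, tids, setdiff(panel$id, tids)))
  }
  best <- pair_tab[1, ]
  pair <- primer_pair(
    primer("F", best$forward_seq, "forward", best$forward_pos),
    primer("R", best$reverse_seq, "reverse", best$reverse_pos))
  rep_ <- screen_panel(pair, truth$panel)
  expect_equal(nrow(rep_$calls), nrow(truth$panel))
  expect_setequal(rep_$calls$id, truth$panel$id)
  # permutation invariance
  withr::local_seed(19)
  shuf <- truth$panel[sample(nrow(truth$panel)), ]
  rep2 <- screen_panel(pair, shuf)
  m <- match(rep_$calls$id, rep2$calls$id)
  expect_equal(rep_$calls$combined_total, rep2$calls$combined_total[m])
  expect_equal(rep_$calls$category, rep2$calls$category[m])
  # screening the reference alone yields a single PERFECT call
  ref_only <- truth$panel[truth$panel$id == "TGT001", ]
  rep3 <- screen_panel(pair, ref_only)
  expect_equal(rep3$calls$category, "PERFECT")
})

test_that("the text report shows dots for identity and counts matching profiles", {
  truth <- simulate_panel()
  pair <- tj_primer_pair()
  ref <- tj_synthetic_reference()
  rep_ <- screen_panel(pair, ref)
  txt <- render_mismatch_alignment(rep_)
  lines <- strsplit(txt, "\n")[[1]]
  # identical template rows render as all dots with count 0
  dotted <- grep("\\.{10,}", lines, value = TRUE)
  expect_true(all(grepl("0$", dotted)))

  # on a mismatching panel, the rendered counts equal the profile totals
  withr::local_seed(20)
  mut <- ref
  ch <- strsplit(mut$residues, "")[[1]]
  ch[240] <- setdiff(c("A", "C", "G", "T"), ch[240])[1]
  ch[245] <- setdiff(c("A", "C", "G", "T"), ch[245])[1]
  mut$residues <- paste(ch, collapse = "")
  mut$id <- "MUT1"
  rep2 <- screen_panel(pair, rbind(ref, mut))
  txt2 <- render_mismatch_alignment(rep2)
  counts <- as.integer(sub("^.*\\s(\\d+)$", "\\1",
                           grep("[.A-Z~-]{20,}  \\d+$",
                                strsplit(txt2, "\n")[[1]], value = TRUE)))
  expect_setequal(counts, c(0, 0, 2, 0))
})
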