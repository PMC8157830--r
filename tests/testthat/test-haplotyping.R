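test_that("identical records collapse to one haplotype; ambiguity is unassignable", {
  p <- seq_panel(sprintf("s%d", 1:6),
                 c(rep("ACGTACGTAC", 5), "ACGTRCGTAC"),
                 country = c(rep("USA", 3), "Canada", "Japan", "USA"))
  out <- collapse_haplotypes(p)
  expect_length(out$haplotypes, 1L)
  expect_equal(out$haplotypes[[1]]$member_ids, sprintf("s%d", 1:5))
  expect_setequal(out$haplotypes[[1]]$countries,
                  c("USA", "Canada", "Japan"))
  expect_equal(out$unassignable, "s6")
  expect_error(collapse_haplotypes(seq_panel(c("a", "b"),
                                             c("ACGT", "ACGTA"))),
               "ragged")
})

test_that("collapse recovers planted haplotypes and is idempotent", {
  truth <- simulate_panel()
  targets <- truth$panel[!is.na(truth$hap_membership$hap), ]
  out <- collapse_haplotypes(targets)
  expect_length(out$haplotypes, length(truth$spec$hap_sizes))
  # memberships equal the simulator truth
  for (h in seq_along(out$haplotypes)) {
    want <- truth$hap_membership$id[
      !is.na(truth$hap_membership$hap) & truth$hap_membership$hap == h]
    expect_setequal(out$haplotypes[[h]]$member_ids, want)
  }
  # member counts sum to the number of assignable records
  expect_equal(sum(vapply(out$haplotypes, function(h)
    length(h$member_ids), integer(1))), nrow(targets))
  # idempotence on the canonical sequences
  canon <- seq_panel(sprintf("h%d", seq_along(out$haplotypes)),
                     vapply(out$haplotypes, `[[`, "", "sequence"))
  out2 <- collapse_haplotypes(canon)
  expect_equal(vapply(out2$haplotypes, `[[`, "", "sequence"),
               vapply(out$haplotypes, `[[`, "", "sequence"))
})

test_that("marker tables name known haplotypes and extend numbering for novel ones", {
  haps <- collapse_haplotypes(seq_panel(
    c("a1", "a2", "b1", "c1"),
    c("ACGTACGTAC", "ACGTACGTAC", "ACGAACGTAC", "ACGTACGTTC")))
  markers <- data.frame(haplotype = c("H2", "H2", "H1"),
                        position = c(4L, 9L, 4L),
                        base = c("T", "A", "A"),
                        stringsAsFactors = FALSE)
  # H2 markers: pos4 T & pos9 A -> first haplotype; H1: pos4 A -> second
  named <- assign_haplotype_names(haps, markers)
  nm <- vapply(named$haplotypes, `[[`, "", "name")
  expect_equal(nm[1], "H2")
  expect_equal(nm[2], "H1")
  expect_equal(nm[3], "H3")  # novel, numbering continues after H2
  expect_equal(named$novel, "H3")

  # empty marker table: all novel, H1..Hk in observation order
  named2 <- assign_haplotype_names(haps, NULL)
  expect_equal(vapply(named2$haplotypes, `[[`, "", "name"),
               c("H1", "H2", "H3"))

  # a haplotype matching two full marker sets invalidates the table
  bad <- data.frame(haplotype = c("H1", "H2"), position = c(1L, 2L),
                    base = c("A", "C"), stringsAsFactors = FALSE)
  expect_error(assign_haplotype_names(haps, bad), "multiple marker sets")
  # marker positions must lie inside the trimmed region
  far <- data.frame(haplotype = "H1", position = 99L, base = "A",
                    stringsAsFactors = FALSE)
  expect_error(assign_haplotype_names(haps, far), "outside")
})

test_that("haplotype networks are minimum spanning trees with deterministic ties", {
  one <- assign_haplotype_names(
    collapse_haplotypes(seq_panel("a", "ACGTACGT")), NULL)
  net1 <- haplotype_network(one)
  expect_equal(nrow(net1$edges), 0L)

  two <- assign_haplotype_names(collapse_haplotypes(
    seq_panel(c("a", "b"), c("ACGTACGT", "ACGTACGA"))), NULL)
  net2 <- haplotype_network(two)
  expect_equal(nrow(net2$edges), 1L)
  expect_equal(net2$edges$weight, 1)

  # edge count is node count - 1 and the graph is connected (a tree)
  truth <- simulate_panel()
  targets <- truth$panel[!is.na(truth$hap_membership$hap), ]
  named <- assign_haplotype_names(collapse_haplotypes(targets), NULL)
  net <- haplotype_network(named)
  expect_equal(nrow(net$edges), nrow(net$nodes) - 1L)
})

test_that("MST weight equals the brute-force minimum over all spanning trees", {
  withr::local_seed(21)
  for (n in c(3, 5, 7)) {
    seqs <- vapply(seq_len(n), function(i) random_dna(12), "")
    if (anyDuplicated(seqs)) next
    haps <- assign_haplotype_names(collapse_haplotypes(
      seq_panel(sprintf("s%d", seq_len(n)), seqs)), NULL)
    net <- haplotype_network(haps)
    expect_equal(net$total_weight, oracle_mst_weight(seqs))
  }
})

test_that("MST weight agrees with igraph on random haplotype sets", {
  withr::local_seed(22)
  for (rep in 1:5) {
    n <- sample(4:9, 1)
    seqs <- unique(vapply(seq_len(n), function(i) random_dna(15), ""))
    haps <- assign_haplotype_names(collapse_haplotypes(
      seq_panel(sprintf("s%d", seq_along(seqs)), seqs)), NULL)
    net <- haplotype_network(haps)
    d <- as.matrix(utils::combn(length(seqs), 2))
    g <- igraph::make_full_graph(length(seqs))
    igraph::E(g)$weight <- apply(d, 2, function(ij) {
      sum(strsplit(seqs[ij[1]], "")[[1]] != strsplit(seqs[ij[2]], "")[[1]])
    })
    mst <- igraph::mst(g)
    expect_equal(net$total_weight, sum(igraph::E(mst)$weight))
  }
})

test_that("regional summaries count PERFECT matches only and lose no record", {
  # a panel in which every record is the reference: 100% in its region
  ref <- tj_synthetic_reference()
  panel <- do.call(rbind, lapply(1:4, function(i) {
    r <- ref; r$id <- sprintf("R%d", i); r
  }))
  panel$region_group <- c("North America", "North America", "Europe",
                          "Europe")
  out <- regional_match_summary(panel, tj_primer_pair())
  expect_equal(out$pct_perfect[out$region == "North America"], 100)
  expect_equal(out$pct_perfect[out$region == "overall"], 100)

  # planted 3'-window variants in a subset: percentage equals the planted
  # fraction, PROBABLE is reported separately, unknown region retained
  mut3 <- function(r, id) {
    ch <- strsplit(r$residues, "")[[1]]
    ch[263] <- setdiff(c("A", "C", "G", "T"), ch[263])[1]  # fwd 3' terminus
    r$residues <- paste(ch, collapse = ""); r$id <- id; r
  }
  mut_mid <- function(r, id) {
    ch <- strsplit(r$residues, "")[[1]]
    ch[240] <- setdiff(c("A", "C", "G", "T"), ch[240])[1]  # internal
    r$residues <- paste(ch, collapse = ""); r$id <- id; r
  }
  panel2 <- rbind(panel,
                  mut3(ref, "M1"), mut3(ref, "M2"), mut_mid(ref, "M3"))
  panel2$region_group[5:7] <- c("Asia", "Asia", NA)
  out2 <- regional_match_summary(panel2, tj_primer_pair())
  expect_equal(out2$pct_perfect[out2$region == "Asia"], 0)
  expect_equal(out2$n[out2$region == "unknown"], 1)
  expect_equal(out2$n_probable[out2$region == "unknown"], 1)
  expect_equal(out2$pct_perfect[out2$region == "overall"],
               round(100 * 4 / 7, 1))
  # overall count equals the sum of regional counts
  expect_equal(sum(out2$n[out2$region != "overall"]),
               out2$n[out2$region == "overall"])
})
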