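test_that("barcoding gap holds for every species at zero divergence", {
  set <- default_set(seed = 7)
  g <- gap_analysis(k2p_matrix(set), "species")
  expect_true(all(g$gap))
  expect_true(all(g$max_intra == 0))
  expect_true(all(g$min_inter > 0))
})

test_that("planted high ZB3 divergence breaks only the Z. bungeanum gap", {
  set <- gen_barcode_set(barcode_scenario(
    within_cultivar_divergence = c(ZB3 = 0.02), seed = 11))
  g <- gap_analysis(k2p_matrix(set), "species")
  expect_false(g$gap[g$group == "Z. bungeanum"])
  expect_true(g$gap[g$group == "Z. armatum"])
  expect_true(g$gap[g$group == "Toddalia asiatica"])
})

test_that("gap analysis preconditions and singleton flagging", {
  set <- default_set(seed = 7)
  za_only <- set[set$species == "Z. armatum"]
  expect_error(gap_analysis(k2p_matrix(za_only), "species"), "2 species")
  # singleton species: intra undefined and flagged NA
  sub <- set[c(which(set$species == "Z. armatum"),
               which(set$species == "Z. bungeanum")[1])]
  g <- gap_analysis(k2p_matrix(sub), "species")
  expect_true(is.na(g$max_intra[g$group == "Z. bungeanum"]))
  expect_true(is.na(g$gap[g$group == "Z. bungeanum"]))
})

test_that("intra ranges match closed form and brute-force enumeration", {
  # planted two-haplotype cultivar differing by 3 transitions
  base <- strsplit(default_set(seed = 2)$seq[1], "")[[1]]
  var <- base
  at <- which(var %in% c("A", "G"))[1:3]
  var[at] <- ifelse(var[at] == "A", "G", "A")
  seqs <- c(paste(base, collapse = ""), paste(base, collapse = ""),
            paste(var, collapse = ""))
  set <- aligned_seq_set(seqs, rep("sp", 3), rep("cv", 3))
  r <- intra_range(k2p_matrix(set), "cultivar")
  usable <- sum(base != "-")
  P <- 3 / usable
  expect_equal(r$min_intra, 0)
  expect_equal(r$max_intra, -0.5 * log(1 - 2 * P), tolerance = 1e-10)

  # random 10-taxon instance vs brute-force pair enumeration
  set.seed(17)
  anc <- sample(c("A", "C", "G", "T"), 80, TRUE)
  seqs <- replicate(10, {
    s <- anc
    at2 <- sample(80, 6)
    s[at2] <- vapply(s[at2], function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1), "")
    paste(s, collapse = "")
  })
  groups <- rep(c("g1", "g2"), each = 5)
  set2 <- aligned_seq_set(seqs, groups, groups)
  r2 <- intra_range(k2p_matrix(set2), "cultivar")
  for (gr in c("g1", "g2")) {
    oracle <- oracle_intra(seqs, groups, gr)
    expect_equal(r2$min_intra[r2$group == gr], min(oracle), tolerance = 1e-12)
    expect_equal(r2$max_intra[r2$group == gr], max(oracle), tolerance = 1e-12)
  }
  # identical-haplotype group -> (0, 0); singleton -> flagged NA
  set3 <- aligned_seq_set(c("ACGT", "ACGT", "AGGT"), rep("s", 3),
                          c("c1", "c1", "c2"))
  r3 <- intra_range(k2p_matrix(set3), "cultivar")
  expect_equal(unlist(r3[r3$group == "c1", c("min_intra", "max_intra")]),
               c(min_intra = 0, max_intra = 0))
  expect_true(is.na(r3$max_intra[r3$group == "c2"]))
})

test_that("diagnostic sites recover the planted insert and SNP positions", {
  set <- default_set(seed = 7)
  rep <- diagnostic_sites(set, "species")
  expect_equal(rep[["Z. bungeanum"]]$variable_sites$position,
               c(105L, 191L, 197L, 203L))
  expect_equal(nrow(rep[["Z. bungeanum"]]$indel_sites), 0)
  expect_equal(rep[["Z. armatum"]]$indel_sites$position, c(29L, 165L, 215L))
  expect_equal(nrow(rep[["Z. armatum"]]$variable_sites), 0)
})

test_that("diagnostic sites equal a brute-force per-column scan", {
  set.seed(23)
  seqs <- replicate(10, paste(sample(c("A", "C", "G", "T", "-", "N"), 60, TRUE,
                                     prob = c(0.22, 0.22, 0.22, 0.22, 0.07, 0.05)),
                              collapse = ""))
  groups <- rep(c("g1", "g2"), each = 5)
  set <- aligned_seq_set(seqs, groups, groups)
  rep <- diagnostic_sites(set, "species")
  oracle <- oracle_diagnostic(seqs, groups)
  for (gr in c("g1", "g2")) {
    got <- sort(c(rep[[gr]]$variable_sites$position, rep[[gr]]$indel_sites$position))
    expect_equal(got, sort(oracle[[gr]]))
  }
})

test_that("an invariant alignment yields an empty diagnostic report", {
  set <- aligned_seq_set(rep("ACGTACGT", 4), rep(c("s1", "s2"), each = 2),
                         rep(c("c1", "c2"), each = 2))
  rep <- diagnostic_sites(set, "species")
  expect_true(all(vapply(rep, function(x) nrow(x$variable_sites) == 0 &&
                                           nrow(x$indel_sites) == 0, logical(1))))
})

test_that("haplotype collapse counts planted variants and is idempotent", {
  set <- gen_barcode_set(barcode_scenario(seed = 3))
  # plant one variant specimen inside ZA1
  i <- which(set$cultivar == "ZA1")[1]
  s <- strsplit(set$seq[i], "")[[1]]
  j <- which(s == "A")[1]
  s[j] <- "G"
  set$seq[i] <- paste(s, collapse = "")
  hc <- haplotype_collapse(set, "cultivar")
  expect_equal(hc$counts$n_haplotypes[hc$counts$group == "ZA1"], 2)
  expect_true(all(hc$counts$n_haplotypes[hc$counts$group != "ZA1"] == 1))
  # idempotence: one representative per haplotype collapses to itself
  reps <- set[!duplicated(hc$haplotype)]
  hc2 <- haplotype_collapse(reps, "cultivar")
  expect_equal(sum(hc2$counts$n_haplotypes), length(reps))
  expect_true(all(hc2$counts$n_haplotypes == hc2$counts$n_specimens))
})

test_that("sequence statistics on trivial and generated inputs", {
  set <- aligned_seq_set(c("GGCC", "ACGT"), c("s1", "s2"), c("c1", "c2"))
  st <- seq_stats(set)
  expect_equal(st$per_record$gc_percent, c(100, 50))
  expect_equal(st$per_record$ungapped_length, c(4L, 4L))

  f <- tempfile(fileext = ".fasta")
  write_alignment(default_set(seed = 9), f)
  st2 <- seq_stats(read_alignment(f))
  expect_true(all(st2$per_record$ungapped_length >= 222 &
                  st2$per_record$ungapped_length <= 227))
})

test_that("ambiguity codes other than N are rejected at construction", {
  expect_error(aligned_seq_set(c("ACGR"), "s", "c"), "disallowed")
  expect_error(aligned_seq_set(c("ACGT", "ACG"), c("s", "s"), c("c", "c")),
               "equal length")
  expect_error(aligned_seq_set(c("ACGT", "ACGT"), c("s", "s"), c("c", "c"),
                               id = c("x", "x")), "unique")
})
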