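test_that("local alignment matches the brute-force oracle on random pairs", {
  set.seed(77)
  for (i in 1:150) {
    a <- random_dna(sample(5:30, 1))
    b <- random_dna(sample(5:30, 1))
    hit <- local_align(a, b, "r")
    expect_equal(hit$score, sw_oracle_both_strands(a, b),
                 info = paste(a, b))
  }
})

test_that("alignment scores follow the scoring scheme on worked cases", {
  set.seed(123)
  query <- random_dna(120)
  read <- substr(query, 31, 80) # 50-nt exact substring
  expect_equal(local_align(read, query)$score, 100) # 50 x 2

  mm <- read
  substr(mm, 25, 25) <- setdiff(c("A", "C", "G", "T"),
                                substr(read, 25, 25))[1]
  sc <- local_align(mm, query)$score
  expect_equal(sc, sw_oracle_both_strands(mm, query))
  expect_equal(sc, 49 * 2 - 3) # one interior mismatch

  # reverse-complement orientation is found
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  hit_rc <- local_align(rc, query)
  expect_equal(hit_rc$score, 100)
  expect_equal(hit_rc$strand, "-")
})

test_that("query-projected base calls report read bases at query positions", {
  set.seed(456)
  query <- random_dna(20)
  read <- substr(query, 1, 10)
  hit <- local_align(read, query)
  expect_equal(hit$query_start, 1L)
  expect_equal(unname(hit$calls[as.character(1:10)]),
               strsplit(read, "")[[1]])

  # a deletion in the read shows as a gap call
  del <- paste0(substr(query, 1, 8), substr(query, 12, 20))
  hit_del <- local_align(del, query)
  if (hit_del$query_end - hit_del$query_start + 1 > 15) {
    expect_true(any(hit_del$calls == "-"))
  }
})

test_that("hit filtering is strict, sorted and capped", {
  mk <- function(id, score) toy_hit(id, c(`1` = "A"), score)
  hits <- list(mk("a", 95), mk("b", 85), mk("c", 75))
  kept <- filter_hits(hits, min_score = 80, cap = 100)
  expect_equal(vapply(kept, `[[`, character(1), "read_id"), c("a", "b"))

  # exactly at the threshold is excluded (strict >)
  expect_length(filter_hits(list(mk("x", 80)), 80, 10), 0L)

  # cap keeps the highest-scoring, ties broken by read id
  many <- lapply(1:150, function(i) mk(sprintf("r%03d", i), 100 + (i %% 3)))
  top <- filter_hits(many, 80, 100)
  expect_length(top, 100L)
  scores <- vapply(top, `[[`, numeric(1), "score")
  expect_true(all(diff(scores) <= 0))
  expect_equal(min(scores), 101)

  expect_length(filter_hits(list(), 80, 100), 0L)
})

test_that("vote tallies cover counts, percent match and undefined positions", {
  ref <- "ACG"
  hits <- list(
    toy_hit("h1", c(`11` = "A", `12` = "C", `13` = "G")),
    toy_hit("h2", c(`11` = "A", `12` = "T", `13` = "G")),
    toy_hit("h3", c(`11` = "A", `12` = "C")),
    toy_hit("h4", c(`11` = "N", `12` = "C"))
  )
  vt <- vote(hits, 11, 13, ref)
  expect_equal(vt$coverage, c(4L, 4L, 2L))
  expect_equal(vt$percent_match, c(75, 75, 100))
  expect_equal(vt$N[1], 1L)
  # base counts sum to coverage
  expect_equal(rowSums(vt[, c("A", "C", "G", "T", "N", "gap")]),
               vt$coverage, ignore_attr = TRUE)

  # all-matching hits give 100 percent everywhere
  allm <- lapply(1:10, function(i) {
    toy_hit(paste0("m", i), c(`11` = "A", `12` = "C", `13` = "G"))
  })
  expect_equal(vote(allm, 11, 13, ref)$percent_match, c(100, 100, 100))

  # 7 of 10 covering reads with the reference base -> 70 percent
  seven <- lapply(1:10, function(i) {
    toy_hit(paste0("s", i), c(`11` = if (i <= 7) "A" else "G"))
  })
  expect_equal(vote(seven, 11, 11, "A")$percent_match, 70)

  # zero coverage is undefined, not zero
  vt0 <- vote(hits, 14, 14, "A")
  expect_true(is.na(vt0$percent_match))
  expect_error(vote(hits, 0, 2, "AAA", query_length = 20), "outside")
  expect_error(vote(hits, 11, 13, "ACGT"), "does not match")
})

test_that("vote percentages are invariant to hit order and duplicates collapse", {
  hits <- list(
    toy_hit("a", c(`5` = "A", `6` = "C")),
    toy_hit("b", c(`5` = "G", `6` = "C")),
    toy_hit("c", c(`5` = "A", `6` = "T"))
  )
  v1 <- vote(hits, 5, 6, "AC")
  v2 <- vote(rev(hits), 5, 6, "AC")
  expect_equal(v1$percent_match, v2$percent_match)
  expect_equal(v1[, c("A", "C", "G", "T")], v2[, c("A", "C", "G", "T")])
})

test_that("consensus calls majority bases, reference on ties, N when empty", {
  hits <- c(
    lapply(1:6, function(i) toy_hit(paste0("t", i),
                                    c(`1` = "A", `2` = "A", `3` = "G"))),
    lapply(1:3, function(i) toy_hit(paste0("u", i),
                                    c(`1` = "A", `2` = "C", `3` = "G")))
  )
  vt <- vote(hits, 1, 3, "ACG")
  cm <- consensus_motif(vt)
  expect_equal(cm$nt, "aag")
  expect_length(cm$ties, 0L)

  # tie at a position resolves to the reference base and is flagged
  tied <- c(
    lapply(1:3, function(i) toy_hit(paste0("v", i), c(`1` = "A"))),
    lapply(1:3, function(i) toy_hit(paste0("w", i), c(`1` = "C")))
  )
  vtt <- vote(tied, 1, 1, "C")
  cmt <- consensus_motif(vtt)
  expect_equal(cmt$nt, "c")
  expect_equal(cmt$ties, 1L)

  # an uncovered codon translates to X
  part <- lapply(1:4, function(i) {
    toy_hit(paste0("p", i), setNames(rep("A", 9), as.character(1:9)))
  })
  vtp <- vote(part, 1, 12, "aaaaaaaaacgg")
  cmp <- consensus_motif(vtp)
  expect_equal(cmp$aa, "KKKX")
  expect_equal(cmp$uncovered, 10:12)
})

test_that("end-to-end read vote recovers a planted motif substitution", {
  motif <- demo_exon_motif()
  sim <- simulate_reads(read_sim_config(
    variants = data.frame(pos = motif[1] + 9, base = "T"),
    n_reads = 200, error_rate = 0.01, seed = 5
  ))
  rv <- read_vote(sim$reads, demo_exon(), motif[1], motif[2])
  expect_equal(rv$consensus$aa, "KKRW")
  expect_equal(rv$consensus$nt, "aagaagagatgg")
  # the variant position rarely matches the human base (error/3 rate)
  expect_lt(rv$vote_table$percent_match[10], 10)
  expect_true(all(rv$vote_table$percent_match[-10] > 90))
})
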