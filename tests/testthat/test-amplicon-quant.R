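fx <- egfp_fixtures()
g81 <- find_protospacers(fx$q81x_cds, 240, editor_profiles("abe8e_sp"))[[1]]
amp <- fx$q81x_cds

test_that("mean-quality filtering is a strict threshold", {
  reads <- make_reads(c(strrep("ACGT", 10), strrep("ACGT", 10), strrep("ACGT", 10)),
                      phred = c(35, 29, 30))
  kept <- filter_by_mean_quality(reads, 30)
  expect_length(kept, 1L)          # Q35 kept; Q29 and mean exactly 30 removed
  expect_identical(names(kept), "r0001")
  expect_equal(mean_phred(reads), c(35, 29, 30))
})

test_that("alignment places exact, mutated and reverse-complement reads", {
  read <- substr(amp, 101, 300)
  a <- align_to_amplicon(read, amp)
  expect_identical(a$strand, "+")
  expect_identical(a$offset, 100L)
  expect_false(a$gapped)
  expect_equal(a$score, 2 * 200)
  rc <- align_to_amplicon(revcomp(read), amp)
  expect_identical(rc$strand, "-")
  expect_identical(rc$offset, 100L)
  expect_identical(rc$oriented, read)
  mut_read <- read
  substr(mut_read, 50, 50) <- if (substr(read, 50, 50) == "A") "C" else "A"
  m <- align_to_amplicon(mut_read, amp)
  expect_equal(m$score, 2 * 199 - 3)   # exactly one mismatch column
  garbage <- strrep("AC", 100)
  expect_true(align_to_amplicon(garbage, amp)$unalignable)
})

test_that("alignment scores match an independent affine-gap DP oracle", {
  subject <- random_dna(80, seed = 21)
  set.seed(22)
  for (i in 1:40) {
    start <- sample(1:50, 1)
    len <- sample(20:30, 1)
    read <- substr(subject, start, start + len - 1)
    # perturb: substitutions and occasional indels
    r <- strsplit(read, "")[[1]]
    nsub <- sample(0:2, 1)
    for (p in sample(seq_along(r), nsub)) r[p] <- sample(c("A", "C", "G", "T"), 1)
    if (runif(1) < 0.3) r <- r[-sample(seq_along(r), 1)]          # deletion
    if (runif(1) < 0.3) {                                          # insertion
      at <- sample(seq_along(r), 1)
      r <- append(r, sample(c("A", "C", "G", "T"), 1), after = at)
    }
    read <- paste(r, collapse = "")
    if (runif(1) < 0.5) read <- revcomp(read)
    got <- align_to_amplicon(read, subject)
    want <- max(oracle_align_score(read, subject),
                oracle_align_score(revcomp(read), subject))
    expect_equal(got$score, want, info = paste("case", i))
  }
})

test_that("editing percent is exact on a constructed read set", {
  tcoord <- 241L
  base <- substr(amp, 151, 400)  # covers the window around the target
  edited <- base
  substr(edited, tcoord - 150L, tcoord - 150L) <- "C"  # T>C on the plus strand
  reads <- make_reads(c(rep(edited, 300), rep(base, 700)))
  res <- quantify_sample(reads, amp, g81)
  expect_equal(res$editing_percent, 30.0)
  expect_identical(res$n_quantified, 1000L)
  expect_identical(res$target_amplicon_position, tcoord)
  # reads all failing the quality filter give a missing, not zero, percent
  low <- make_reads(rep(base, 5), phred = 20)
  res0 <- quantify_sample(low, amp, g81)
  expect_identical(res0$n_quantified, 0L)
  expect_true(is.na(res0$editing_percent))
  # a guide absent from the amplicon is an inconsistent input
  foreign <- guide_design(strrep("ACGT", 5), "+", 0, "AGG", 5)
  expect_error(quantify_sample(reads, amp, foreign), "not found")
})

test_that("read accounting is conserved across filter stages", {
  base <- substr(amp, 151, 400)
  # one clean read, one low-quality, one garbage, one with a deletion in
  # the window, one with a deletion far outside the window
  del_in <- paste0(substr(base, 1, 89), substr(base, 92, 250))    # near target
  del_out <- paste0(substr(base, 1, 230), substr(base, 234, 250))
  reads <- make_reads(c(base, base, strrep("TA", 125), del_in, del_out),
                      phred = c(37, 25, 37, 37, 37))
  res <- quantify_sample(reads, amp, g81)
  expect_identical(res$n_total, 5L)
  expect_identical(res$n_removed_quality, 1L)
  expect_identical(res$n_unalignable, 1L)
  expect_identical(res$n_window_indel, 1L)
  expect_identical(res$n_total,
                   res$n_pass_quality + res$n_removed_quality)
  expect_identical(res$n_pass_quality,
                   res$n_quantified + res$n_unalignable +
                     res$n_window_indel + res$n_window_not_covered)
  # substitution-table counts at each position sum to the quantified reads
  tab <- res$substitution_table
  sums <- tapply(tab$count, tab$position, sum)
  expect_true(all(sums == res$n_quantified))
  # with the permissive indel policy the windowed-indel read is retained
  res2 <- quantify_sample(reads, amp, g81,
                          quant_config(indel_policy = "count_all"))
  expect_identical(res2$n_window_indel, 0L)
  expect_identical(res2$n_quantified, res$n_quantified + 1L)
})

test_that("quantification is invariant to reverse-complementing every read", {
  cfg <- amplicon_sim_config(amp, g81, edit_fraction = 0.25, n_reads = 400,
                             per_base_error = 0.002, seed = 5)
  sim <- simulate_amplicon_reads(cfg)
  res_f <- quantify_sample(sim$reads, amp, g81)
  flipped <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::reverseComplement(methods::as(sim$reads, "DNAStringSet")),
    Biostrings::PhredQuality(vapply(as.character(Biostrings::quality(sim$reads)),
                                    function(s) paste(rev(strsplit(s, "")[[1]]),
                                                      collapse = ""), "",
                                    USE.NAMES = FALSE)))
  res_r <- quantify_sample(flipped, amp, g81)
  expect_equal(res_r$editing_percent, res_f$editing_percent)
  expect_identical(res_r$n_quantified, res_f$n_quantified)
  expect_equal(res_r$substitution_table, res_f$substitution_table)
})

test_that("the editing estimator concentrates as read depth grows", {
  qs <- c(0.05, 0.3, 0.98)
  seeds <- 1:20
  cover <- 0L; total <- 0L
  for (q in qs) {
    err_small <- err_big <- numeric(length(seeds))
    for (i in seq_along(seeds)) {
      for (n in c(1000L, 10000L)) {
        cfg <- amplicon_sim_config(amp, g81, edit_fraction = q, n_reads = n,
                                   per_base_error = 0.001,
                                   fraction_low_quality = 0,
                                   seed = 1000L * i + n %/% 1000L)
        sim <- simulate_amplicon_reads(cfg)
        est <- quantify_sample(sim$reads, amp, g81)$editing_percent / 100
        if (n == 1000L) err_small[i] <- abs(est - q) else err_big[i] <- abs(est - q)
        if (n == 10000L) {
          total <- total + 1L
          if (abs(est - q) <= 1.96 * sqrt(q * (1 - q) / n) + 0.0015)
            cover <- cover + 1L
        }
      }
    }
    expect_lt(mean(err_big), mean(err_small))
  }
  expect_gte(cover / total, 0.90)
})
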