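test_that("single-base edits apply and round-trip", {
  expect_identical(apply_edit("ATGCAG", 4, "C", "T", "+"), "ATGTAG")
  # minus-strand C->T is G->A on the stored plus strand
  expect_identical(apply_edit("ATGTGG", 5, "C", "T", "-"), "ATGTAG")
  s <- "ATGCAGTTT"
  expect_identical(apply_edit(apply_edit(s, 4, "C", "T", "+"), 4, "T", "C", "+"), s)
  expect_error(apply_edit("ATGCAG", 4, "A", "T", "+"), "expected")
  expect_error(apply_edit("ATG", 9, "C", "T", "+"), "out of bounds")
})

test_that("the screen finds the codon-81 stop switch with its printed guide", {
  fx <- egfp_fixtures()
  cands <- enumerate_stop_switch_sites(fx$wt_cds, editor_profiles("be4max_sp_ng"),
                                       list(editor_profiles("abe8e_sp")))
  c81 <- Filter(function(x) x$codon_index == 81, cands)
  expect_length(c81, 1L)
  c81 <- c81[[1]]
  expect_identical(c81$wt_codon, "CAG")
  expect_identical(c81$installed_codon, "TAG")
  expect_identical(c81$edit_cds_position, 241L)
  expect_identical(c81$install_guides[[1]]$spacer, "GAAGCAGCACGACTTCTTCA")
  # every candidate translates to a stop at its codon and nowhere else new
  for (x in cands) {
    mut <- apply_edit(fx$wt_cds, x$edit_cds_position, "C", "T", x$edit_strand)
    aa_wt <- strsplit(translate_cds(fx$wt_cds), "")[[1]]
    aa_mut <- strsplit(translate_cds(mut), "")[[1]]
    expect_identical(aa_mut[x$codon_index], "*")
    expect_identical(aa_mut[-x$codon_index], aa_wt[-x$codon_index])
  }
})

test_that("screen edge cases behave", {
  permissive <- editor_profile("permissive", "C", "T", 1, 20, "N", 20)
  toy <- paste0("ATGCGA", strrep("TTC", 8))
  cands <- enumerate_stop_switch_sites(toy, permissive)
  expect_length(cands, 1L)
  expect_identical(cands[[1]]$codon_index, 2L)
  expect_identical(cands[[1]]$installed_codon, "TGA")
  # a CDS with none of the four switchable codons yields nothing
  expect_length(enumerate_stop_switch_sites("ATGTTTTTCTTA", permissive), 0L)
  expect_error(enumerate_stop_switch_sites(toy, editor_profiles("abe8e_sp")),
               "CBE-type")
})

test_that("reversion design recovers the printed correction guides", {
  fx <- egfp_fixtures()
  cands <- enumerate_stop_switch_sites(fx$wt_cds, editor_profiles("be4max_sp_ng"))
  c81 <- Filter(function(x) x$codon_index == 81, cands)[[1]]
  g <- design_reversion_guides(fx$q81x_cds, c81, editor_profiles("abe8e_sp"))
  spacers <- vapply(g, function(x) x$spacer, "")
  tpos <- vapply(g, function(x) x$target_position, 0L)
  i <- match("CGTGCTACTTCATGTGGTCG", spacers)
  expect_false(is.na(i))
  expect_identical(tpos[i], 7L)
  expect_identical(g[[i]]$pam_seq, "GGG")
  sa <- design_reversion_guides(fx$q81x_cds, c81, editor_profiles("sa_abe8e"))
  expect_true("AGTCGTGCTACTTCATGTGGT" %in% vapply(sa, function(x) x$spacer, ""))
  # narrowing the window to a single position filters to that target
  narrow <- editor_profile("narrow", "A", "G", 7, 7, "NGG", 20)
  g7 <- design_reversion_guides(fx$q81x_cds, c81, narrow)
  expect_true(length(g7) >= 1)
  expect_true(all(vapply(g7, function(x) x$target_position, 0L) == 7L))
  expect_error(design_reversion_guides(fx$wt_cds, c81, editor_profiles("abe8e_sp")),
               "expected installed codon")
})

test_that("bystander counting matches the printed spacers", {
  fx <- egfp_fixtures()
  cands <- enumerate_stop_switch_sites(fx$wt_cds, editor_profiles("be4max_sp_ng"),
                                       list(editor_profiles("abe8e_sp")))
  c81 <- Filter(function(x) x$codon_index == 81, cands)[[1]]
  g1 <- Filter(function(x) x$spacer == "CGTGCTACTTCATGTGGTCG",
               c81$reversion_guides[["abe8e_sp"]])[[1]]
  b <- count_bystanders(g1, editor_profiles("abe8e_sp"), fx$q81x_cds)
  expect_identical(b$n_bystanders, 0L)  # spacer adenines only at 7 and 12
  expect_identical(b$annotations$protospacer_position, 7L)
  expect_true(b$annotations$is_target)
  # the install guide carries one bystander C at window position 8
  ig <- c81$install_guides[[1]]
  bi <- count_bystanders(ig, editor_profiles("be4max_sp_ng"), fx$wt_cds)
  expect_identical(bi$n_bystanders, 1L)
  expect_identical(setdiff(bi$annotations$protospacer_position, 5L), 8L)
  # consequences recompute from translation
  expect_identical(bi$annotations$consequence[bi$annotations$is_target], "nonsense")
  expect_error(count_bystanders(g1, editor_profiles("abe8e_sp"), fx$wt_cds),
               "does not match context")
})

test_that("candidate ranking is deterministic with stated tie-breaks", {
  mk <- function(k, bys, profiles_with_guides = 1L) {
    g <- guide_design("ACGTACGTACGTACGTACGT", "+", 0, "AGG", 5)
    k <- as.integer(k)
    structure(list(codon_index = k, wt_codon = "CAG", installed_codon = "TAG",
                   edit_cds_position = 3L * k - 2L, edit_strand = "+",
                   install_guides = list(g),
                   reversion_guides = stats::setNames(
                     rep(list(list(g)), profiles_with_guides),
                     paste0("p", seq_len(profiles_with_guides))),
                   min_reversion_bystanders = bys),
              class = "stop_switch_candidate")
  }
  r <- rank_candidates(list(mk(10, 2L), mk(20, 0L), mk(30, 1L)))
  expect_identical(vapply(r, function(x) x$min_reversion_bystanders, 0L),
                   c(0L, 1L, 2L))
  # tie at 0: more orthologue coverage wins, then the 5'-most codon
  r2 <- rank_candidates(list(mk(10, 0L, 1L), mk(5, 0L, 2L)))
  expect_identical(vapply(r2, function(x) x$codon_index, 0L), c(5L, 10L))
  r3 <- rank_candidates(list(mk(10, 0L), mk(5, 0L)))
  expect_identical(vapply(r3, function(x) x$codon_index, 0L), c(5L, 10L))
  # no-reversion candidates sink to the bottom, flagged
  r4 <- rank_candidates(list(mk(5, NA_integer_), mk(10, 3L)))
  expect_identical(vapply(r4, function(x) x$codon_index, 0L), c(10L, 5L))
  expect_true(r4[[2]]$no_reversion)
})

test_that("the EGFP screen ranks the codon-81 candidate first", {
  fx <- egfp_fixtures()
  ranked <- rank_candidates(enumerate_stop_switch_sites(
    fx$wt_cds, editor_profiles("be4max_sp_ng"),
    list(editor_profiles("abe8e_sp"), editor_profiles("sa_abe8e"),
         editor_profiles("sauri_abe"))))
  expect_identical(ranked[[1]]$codon_index, 81L)
  expect_identical(ranked[[1]]$min_reversion_bystanders, 0L)
})

test_that("install-then-revert restores random ORFs exactly", {
  prof_cbe <- editor_profiles("be4max_sp_ng")
  prof_abe <- editor_profiles("abe8e_sp")
  for (seed in 1:10) {
    orf <- random_orf(60, seed = seed)
    cands <- enumerate_stop_switch_sites(orf, prof_cbe, list(prof_abe))
    for (x in cands) {
      mut <- apply_edit(orf, x$edit_cds_position, "C", "T", x$edit_strand)
      for (g in x$reversion_guides[["abe8e_sp"]]) {
        coord <- x$edit_cds_position
        back <- apply_edit(mut, coord, "A", "G", g$strand)
        expect_identical(back, orf)
      }
    }
  }
})

test_that("screen agrees with the brute-force single-edit oracle", {
  prof <- editor_profiles("be4max_sp_ng")
  key <- function(x) paste(x$codon_index, x$installed_codon,
                           x$edit_cds_position, x$edit_strand)
  for (seed in 1:10) {
    orf <- random_orf(100, seed = seed + 500)
    got <- enumerate_stop_switch_sites(orf, prof)
    want <- oracle_stop_switch(orf, prof)
    expect_setequal(vapply(got, key, ""), vapply(want, key, ""))
  }
})

test_that("wider windows and laxer PAMs never lose candidates or guides", {
  base <- editor_profiles("be4max_sp_ngg")
  wider <- editor_profile("w", "C", "T", 3, 9, "NGG", 20)
  laxer <- editor_profile("l", "C", "T", 4, 8, "NG", 20)
  laxest <- editor_profile("ll", "C", "T", 4, 8, "N", 20)
  key <- function(x) paste(x$codon_index, x$installed_codon, x$edit_cds_position)
  for (seed in 1:6) {
    orf <- random_orf(80, seed = seed + 900)
    k0 <- vapply(enumerate_stop_switch_sites(orf, base), key, "")
    expect_true(all(k0 %in% vapply(enumerate_stop_switch_sites(orf, wider), key, "")))
    k1 <- vapply(enumerate_stop_switch_sites(orf, laxer), key, "")
    expect_true(all(k0 %in% k1))
    expect_true(all(k1 %in% vapply(enumerate_stop_switch_sites(orf, laxest), key, "")))
    # guide-level monotonicity at a fixed site
    site <- sample(20:200, 1)
    s <- random_dna(300, seed = seed)
    g_ngg <- vapply(find_protospacers(s, site, editor_profiles("be4max_sp_ngg")),
                    guide_key, "")
    g_ng <- vapply(find_protospacers(s, site, laxer), guide_key, "")
    expect_true(all(g_ngg %in% g_ng))
  }
})
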