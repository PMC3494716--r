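motifs <- hvr1_motifs()
markers <- rflp_markers()

test_that("HVS-I motif calls match the classic Eurasian motifs", {
  expect_identical(call_from_hvr1(prof("k", c(16093, 16224, 16311, 16319)),
                                  motifs)$haplogroup, "K")
  expect_identical(call_from_hvr1(prof("j", c(16069, 16126)),
                                  motifs)$haplogroup, "J")
  expect_identical(call_from_hvr1(prof("u", c(16129, 16256, 16270, 16304, 16399)),
                                  motifs)$haplogroup, "U5a1")
  ref_like <- call_from_hvr1(prof("e", integer()), motifs)
  expect_match(ref_like$haplogroup, "reference-like")
  expect_true(ref_like$low_confidence)
  expect_error(call_from_hvr1(prof("x", 16223),
                              motifs[0, , drop = FALSE]), "empty")
})

test_that("the motif caller reproduces the reported HVS-I haplogroup for all 19 fixture samples", {
  recs <- altai_pazyryk()
  calls <- call_haplogroups(recs, motifs, markers)
  reported <- vapply(recs, `[[`, "", "reported_hvr1")
  expect_identical(calls$hvr1, reported)
})

test_that("RFLP states call haplogroups via diagnostic hits and exclusions", {
  expect_identical(call_from_rflp(rflp_observation("HaeIII", 663, "present"),
                                  markers, motifs)$haplogroup, "A")
  expect_identical(call_from_rflp(rflp_observation("AluI", 5176, "absent"),
                                  markers, motifs)$haplogroup, "D")
  all_missing <- rflp_observation("HaeIII", 663, "missing")
  expect_identical(call_from_rflp(all_missing, markers, motifs)$haplogroup,
                   "undetermined")
  expect_identical(call_from_rflp(NULL, markers, motifs)$haplogroup,
                   "undetermined")
  # U (12308 present) and K (9052 absent) are nested: narrowest wins
  ku <- rbind(rflp_observation("HinfI", 12308, "present"),
              rflp_observation("HaeII", 9052, "absent"))
  expect_identical(call_from_rflp(ku, markers, motifs)$haplogroup, "K")
  # exclusion path: 7025 present rules out H; with 4577 present -> HV
  hv <- rbind(rflp_observation("AluI", 7025, "present"),
              rflp_observation("NlaIII", 4577, "present"))
  expect_identical(call_from_rflp(hv, markers, motifs)$haplogroup, "HV")
  r0 <- rflp_observation("AluI", 7025, "present")
  expect_identical(call_from_rflp(r0, markers, motifs)$haplogroup, "R0")
  # incompatible simultaneous diagnostics raise a conflict naming both
  conflict <- rbind(rflp_observation("HaeIII", 663, "present"),
                    rflp_observation("HindII", 13259, "absent"))
  expect_error(call_from_rflp(conflict, markers, motifs), "A.*C|C.*A")
})

test_that("combined calls take the deeper label when concordant and flag discordance", {
  u5a1 <- call_from_hvr1(prof("u", c(16256, 16270, 16399)), motifs)
  u <- call_from_rflp(rflp_observation("HinfI", 12308, "present"),
                      markers, motifs)
  cc <- combine_calls(u5a1, u, motifs)
  expect_identical(cc$haplogroup, "U5a1")
  expect_true(cc$concordant)

  g2a <- call_from_hvr1(prof("g", c(16223, 16227, 16278, 16362)), motifs)
  g <- call_from_rflp(rflp_observation("HaeII", 4830, "present"),
                      markers, motifs)
  expect_identical(combine_calls(g2a, g, motifs)$haplogroup, "G2a")
  expect_true(combine_calls(g2a, g, motifs)$concordant)

  j <- call_from_hvr1(prof("j", c(16069, 16126)), motifs)
  und <- call_from_rflp(NULL, markers, motifs)
  cc2 <- combine_calls(j, und, motifs)
  expect_identical(cc2$haplogroup, "J")
  expect_true(is.na(cc2$concordant))

  a_rflp <- call_from_rflp(rflp_observation("HaeIII", 663, "present"),
                           markers, motifs)
  cc3 <- combine_calls(u5a1, a_rflp, motifs)
  expect_identical(cc3$haplogroup, "U5a1")
  expect_false(cc3$concordant)
})

test_that("the combined caller reports concordance (or not-evaluable) for every fixture sample", {
  calls <- call_haplogroups(altai_pazyryk(), motifs, markers)
  expect_true(all(calls$concordant | is.na(calls$concordant)))
  expect_identical(sum(is.na(calls$concordant)), 1L)  # the RFLP-less sample
})

test_that("private variants at non-motif positions never change the top call", {
  non_motif <- setdiff(16051:16400, unique(unlist(motifs$motif)))
  recs <- altai_pazyryk()
  set.seed(31)
  for (k in 1:50) {
    r <- recs[[sample(length(recs), 1)]]
    extra <- sample(setdiff(non_motif, r$profile$positions), 1)
    perturbed <- prof(r$sample_id, c(r$profile$positions, extra))
    expect_identical(call_from_hvr1(perturbed, motifs)$haplogroup,
                     call_from_hvr1(r$profile, motifs)$haplogroup)
  }
})
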