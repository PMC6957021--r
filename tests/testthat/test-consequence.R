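test_that("within-codon joint edits reproduce the published worked annotations", {
  fx <- simulated_mnv_fixture(seed = 1)
  ref <- fx$reference
  txa <- fx$transcripts[[1]]                     # 444-codon HNF4A-like
  txb <- fx$transcripts[[2]]                     # 396-codon isoform

  # CTG -> TTC at codon 280: naive edits are both silent, joint is missense
  naive1 <- annotate_variant(txa, ref, data.frame(c_position = 838, alt = "T"))
  naive2 <- annotate_variant(txa, ref, data.frame(c_position = 840, alt = "C"))
  joint <- annotate_variant(txa, ref,
                            data.frame(c_position = c(838, 840),
                                       alt = c("T", "C")))
  expect_equal(naive1$hgvs_c, "c.838C>T")
  expect_equal(naive1$hgvs_p, "p.Leu280Leu")
  expect_equal(naive2$hgvs_p, "p.Leu280Leu")
  expect_equal(joint$hgvs_c, "c.838_840delinsTTC")
  expect_equal(joint$hgvs_p, "p.Leu280Phe")
  expect_equal(joint$effect_class, "missense")

  # TCC -> AGC at codon 356: two missense SNVs collapse to a synonymous MNV
  s1 <- annotate_variant(txa, ref, data.frame(c_position = 1066, alt = "A"))
  s2 <- annotate_variant(txa, ref, data.frame(c_position = 1067, alt = "G"))
  sj <- annotate_variant(txa, ref,
                         data.frame(c_position = c(1066, 1067),
                                    alt = c("A", "G")))
  expect_equal(s1$hgvs_p, "p.Ser356Thr")
  expect_equal(s2$hgvs_p, "p.Ser356Cys")
  expect_equal(sj$hgvs_c, "c.1066_1067delinsAG")
  expect_equal(sj$hgvs_p, "p.Ser356Ser")
  expect_equal(sj$effect_class, "synonymous")

  # TCT -> TGA at codon 421: nonsense only when treated jointly
  nj <- annotate_variant(txa, ref,
                         data.frame(c_position = c(1262, 1263),
                                    alt = c("G", "A")))
  expect_equal(nj$hgvs_c, "c.1262_1263delinsGA")
  expect_equal(nj$hgvs_p, "p.Ser421*")
  expect_equal(nj$effect_class, "stop_gained")
  expect_equal(annotate_variant(txa, ref,
                                data.frame(c_position = 1262, alt = "G"))$hgvs_p,
               "p.Ser421Cys")
  expect_equal(annotate_variant(txa, ref,
                                data.frame(c_position = 1263, alt = "A"))$hgvs_p,
               "p.Ser421Ser")

  # AAG -> AGT at codon 425: a third missense distinct from either naive call
  kj <- annotate_variant(txa, ref,
                         data.frame(c_position = c(1274, 1275),
                                    alt = c("G", "T")))
  expect_equal(kj$hgvs_c, "c.1274_1275delinsGT")
  expect_equal(kj$hgvs_p, "p.Lys425Ser")

  # TAA -> TGG at the stop codon: retained stop per SNV, stop loss jointly
  t1 <- annotate_variant(txb, ref, data.frame(c_position = 1187, alt = "G"))
  t2 <- annotate_variant(txb, ref, data.frame(c_position = 1188, alt = "G"))
  tj <- annotate_variant(txb, ref,
                         data.frame(c_position = c(1187, 1188),
                                    alt = c("G", "G")))
  expect_equal(t1$hgvs_p, "p.*396*")
  expect_equal(t2$hgvs_p, "p.*396*")
  expect_equal(tj$effect_class, "stop_lost")
  expect_equal(tj$extension_length, 26L)
  expect_equal(tj$hgvs_p, "p.*396Trpext*26")
})

test_that("the clinical codon pairs reproduce the published protein annotations", {
  cases <- list(
    list(wt = "GCC", var = "TTC", num = 752,
         naive = c("p.Ala752Ser", "p.Ala752Val"), merged = "p.Ala752Phe"),
    list(wt = "GAT", var = "TCT", num = 615,
         naive = c("p.Asp615Tyr", "p.Asp615Ala"), merged = "p.Asp615Ser"),
    list(wt = "GAG", var = "AGG", num = 421,
         naive = c("p.Glu421Lys", "p.Glu421Gly"), merged = "p.Glu421Arg"),
    list(wt = "TAC", var = "CAA", num = 61,
         naive = c("p.Tyr61His", "p.Tyr61*"), merged = "p.Tyr61Gln"))
  for (cs in cases) {
    got <- annotate_codon_change(cs$wt, cs$var, cs$num)
    expect_setequal(got$naive, cs$naive)
    expect_equal(got$merged, cs$merged)
  }
  # the stop-gained naive call makes the fourth pair a false-positive risk
  expect_equal(annotate_codon_change("TAC", "CAA", 61)$category,
               "false_positive_risk")
  expect_equal(annotate_codon_change("GCC", "TTC", 752)$category,
               "changed_effect")
})

test_that("joint annotation equals a full-CDS retranslation oracle on random cases", {
  skip_if_not_installed("seqinr")
  set.seed(11)
  n_checked <- 0
  for (seed in 1:60) {
    rt <- random_manual_tx(seed + 500)
    n_codons <- nchar(rt$cds) / 3
    for (rep in 1:5) {
      n_edits <- sample(1:3, 1)
      cpos <- sample(4:(3 * (n_codons - 1)), n_edits)   # avoid start/stop codon
      refb <- vapply(cpos, function(p) substr(rt$cds, p, p), "")
      altb <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
      edits <- data.frame(c_position = cpos, alt = altb)
      cons <- annotate_variant(rt$tx, rt$ref, edits)
      want <- oracle_retranslate(rt$cds, edits)
      expect_equal(sort(cons$codon_numbers), sort(want$codon_number))
      m <- match(cons$codon_numbers, want$codon_number)
      expect_equal(cons$ref_aa, want$ref_aa[m])
      expect_equal(cons$alt_aa, want$alt_aa[m])
      # genomic-space edits give the same answer (strand invariance of input)
      gpos <- cds_to_genomic(rt$tx, cpos)
      galt <- if (rt$tx$strand == "-") vapply(altb, revcomp, "") else altb
      cons_g <- annotate_variant(rt$tx, rt$ref,
                                 data.frame(pos = gpos, alt = galt))
      expect_equal(cons_g$hgvs_c, cons$hgvs_c)
      expect_equal(cons_g$hgvs_p, cons$hgvs_p)
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 300)
})

test_that("invalid edits are rejected with precise errors", {
  rt <- random_manual_tx(9)
  refbase <- substr(rt$cds, 10, 10)
  expect_error(annotate_variant(rt$tx, rt$ref,
                                data.frame(c_position = 10, alt = refbase)),
               "not a variant")
  expect_error(annotate_variant(rt$tx, rt$ref,
                                data.frame(c_position = 10000, alt = "A")),
               "outside CDS")
  expect_error(annotate_variant(rt$tx, rt$ref,
                                data.frame(c_position = c(10, 10),
                                           alt = c("A", "C"))),
               "non-overlapping")
  bad_g <- min(rt$tx$exons$start) - 3
  expect_error(annotate_variant(rt$tx, rt$ref,
                                data.frame(pos = bad_g, alt = "A")),
               "not in the CDS")
})

test_that("stop-loss extension counts codons to the next in-frame stop", {
  nonstop <- "CCT"
  for (k in 1:10) {
    ds <- paste0(strrep(nonstop, k - 1), "TAA", strrep(nonstop, 3))
    expect_equal(stop_extension_length(ds), k)
  }
  expect_equal(stop_extension_length("TAAGGG"), 1L)     # immediate stop
  expect_true(is.na(stop_extension_length(strrep(nonstop, 8))))
  expect_true(is.na(stop_extension_length("")))
  # without a reachable stop the p. string degrades to ext*? instead of failing
  ref <- make_manual_reference()
  txm <- manual_minus_tx(downstream = strrep("CCT", 6))
  # codon 4 of ATG TAC AAA TAA is the stop; TAA -> CAA (c.10 T>C, genomic 9 A>G)
  cons <- annotate_variant(txm, ref, data.frame(c_position = 10, alt = "C"))
  expect_equal(cons$effect_class, "stop_lost")
  expect_equal(cons$hgvs_p, "p.*4Glnext*?")
  txm2 <- manual_minus_tx(downstream = paste0("CCTCCT", "TGA", "CCT"))
  cons2 <- annotate_variant(txm2, ref, data.frame(c_position = 10, alt = "C"))
  expect_equal(cons2$extension_length, 3L)
  expect_equal(cons2$hgvs_p, "p.*4Glnext*3")
})

test_that("discordance categories follow the severity rule", {
  fx <- simulated_mnv_fixture(seed = 1)
  ref <- fx$reference
  txa <- fx$transcripts[[1]]
  ann <- function(cpos, alt) annotate_variant(txa, ref,
                                              data.frame(c_position = cpos,
                                                         alt = alt))
  # {synonymous, synonymous} -> missense: under-called, false negative risk
  d1 <- classify_discordance(list(ann(838, "T"), ann(840, "C")),
                             ann(c(838, 840), c("T", "C")))
  expect_equal(d1$category, "false_negative_risk")
  # {missense, missense} -> synonymous: over-called, false positive risk
  d3 <- classify_discordance(list(ann(1066, "A"), ann(1067, "G")),
                             ann(c(1066, 1067), c("A", "G")))
  expect_equal(d3$category, "false_positive_risk")
  # {missense, missense} -> a different missense: changed effect
  d5 <- classify_discordance(list(ann(1274, "G"), ann(1275, "T")),
                             ann(c(1274, 1275), c("G", "T")))
  expect_equal(d5$category, "changed_effect")
  expect_equal(d5$severity_naive_max, d5$severity_merged)
  # edits in distinct codons decompose into the naive annotations
  set.seed(21)
  n_conc <- 0
  for (seed in 1:25) {
    rt <- random_manual_tx(seed + 900)
    n_codons <- nchar(rt$cds) / 3
    codons <- sample(2:(n_codons - 1), 2)
    cpos <- (codons - 1) * 3 + sample(1:3, 2, replace = TRUE)
    refb <- vapply(cpos, function(p) substr(rt$cds, p, p), "")
    altb <- vapply(refb, function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    naive <- lapply(1:2, function(k)
      annotate_variant(rt$tx, rt$ref,
                       data.frame(c_position = cpos[k], alt = altb[k])))
    merged <- annotate_variant(rt$tx, rt$ref,
                               data.frame(c_position = cpos, alt = altb))
    expect_setequal(merged$alt_aa,
                    vapply(naive, function(x) x$alt_aa, ""))
    if (classify_discordance(naive, merged)$category == "concordant")
      n_conc <- n_conc + 1
  }
  # decomposable multi-codon pairs are always concordant
  expect_equal(n_conc, 25)
})

test_that("hgvs strings are regenerable from the consequence fields", {
  fx <- simulated_mnv_fixture(seed = 1)
  cons <- annotate_variant(fx$transcripts[[1]], fx$reference,
                           data.frame(c_position = c(838, 840),
                                      alt = c("T", "C")))
  regen <- hgvs_strings(cons)
  expect_equal(unname(regen["hgvs_c"]), cons$hgvs_c)
  expect_equal(unname(regen["hgvs_p"]), cons$hgvs_p)
})
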