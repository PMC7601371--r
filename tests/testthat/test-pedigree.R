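# Cohort construction, PED I/O, nuclear decomposition, phenotype masking.

test_that("cohort validation rejects structural defects", {
  base <- nuclear_family_rows("F1", 2)

  bad <- base
  bad$father_id[3] <- "GHOST"
  expect_error(cohort(bad), "unresolved father.*F1_C1")

  expect_error(cohort(rbind(base, base[3, ])), "duplicate")

  # a parent that is its own descendant
  cyc <- rbind(
    ind_row("X", father_id = "Y", mother_id = "Z", sex = "male"),
    ind_row("Y", father_id = "X", mother_id = "Z", sex = "male"),
    ind_row("Z", sex = "female"))
  expect_error(cohort(cyc), "cycl")

  one_parent <- base
  one_parent$mother_id[3] <- NA
  expect_error(cohort(one_parent), "exactly one recorded parent")

  swapped <- base
  swapped$father_id[3:4] <- "F1_P1"
  swapped$mother_id[3:4] <- "F1_P0"
  expect_error(cohort(swapped), "incompatible sex")

  neg_age <- base
  neg_age$age_years[3] <- -1
  expect_error(cohort(neg_age), "negative age")
})

test_that("pedigree files round-trip through write_pedigree/read_pedigree", {
  rows <- rbind(nuclear_family_rows("F1", 3, k = 2),
                nuclear_family_rows("F2", 2))
  rows$age_years[rows$id == "F1_C1"] <- 12.5
  rows$goitre[rows$id == "F1_C2"] <- "visible"
  rows$alive[rows$id == "F2_C2"] <- FALSE
  rows$phenotype[rows$id == "F2_C2"] <- "unknown"
  coh <- cohort(rows)

  ped <- withr::local_tempfile(fileext = ".ped")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(coh, ped, tsv)
  back <- read_pedigree(ped, tsv)
  expect_identical(back$individuals, coh$individuals)
  expect_identical(back$phenotyped_count, coh$phenotyped_count)

  # missing ages survive the round trip as the NA token
  expect_true(is.na(back$individuals$age_years[back$individuals$id == "F1_C3"]))
  expect_equal(back$individuals$age_years[back$individuals$id == "F1_C1"], 12.5)

  # empty cohort gives header-only files that read back empty
  empty <- cohort(ind_row(character(0)))
  write_pedigree(empty, ped, tsv)
  expect_identical(nrow(read_pedigree(ped, tsv)$individuals), 0L)
})

test_that("read_pedigree rejects sidecar/pedigree mismatches", {
  coh <- cohort(nuclear_family_rows("F1", 2))
  ped <- withr::local_tempfile(fileext = ".ped")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(coh, ped, tsv)

  side <- read.delim(tsv, colClasses = "character")
  side$id[1] <- "NOT_IN_PED"
  write.table(side, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_pedigree(ped, tsv), "unknown individual")

  # PED row whose father is absent from the file
  coh2 <- cohort(nuclear_family_rows("F1", 2))
  write_pedigree(coh2, ped, tsv)
  writeLines(sub("F1_P0\tF1_P1", "MISSING_DAD\tF1_P1", readLines(ped)), ped)
  expect_error(read_pedigree(ped, tsv), "unresolved")
})

test_that("split_nuclear partitions offspring into per-couple sibships", {
  mono <- cohort(nuclear_family_rows("F1", 3))
  expect_identical(nrow(mono$nuclear), 1L)
  expect_identical(mono$nuclear$sibship_size, 3L)

  # bigamous father: one nuclear family per wife
  rows <- rbind(ind_row("DAD", sex = "male"),
                ind_row("W1", sex = "female"), ind_row("W2", sex = "female"),
                ind_row("K1", father_id = "DAD", mother_id = "W1"),
                ind_row("K2", father_id = "DAD", mother_id = "W1"),
                ind_row("K3", father_id = "DAD", mother_id = "W2"),
                ind_row("K4", father_id = "DAD", mother_id = "W2"),
                ind_row("K5", father_id = "DAD", mother_id = "W2"))
  big <- cohort(rows)
  expect_identical(nrow(big$nuclear), 2L)
  expect_setequal(big$nuclear$sibship_size, c(2L, 3L))

  # three generations: grandparent couple and parent couple
  tri <- cohort(three_generation_rows())
  expect_identical(nrow(tri$nuclear), 2L)
  off <- sort(unlist(tri$nuclear$offspring_ids))
  non_founders <- sort(tri$individuals$id[!is.na(tri$individuals$father_id)])
  expect_identical(off, non_founders)

  # sibship size counts living offspring only
  rows <- nuclear_family_rows("F1", 4)
  rows$alive[rows$id == "F1_C4"] <- FALSE
  rows$phenotype[rows$id == "F1_C4"] <- "unknown"
  expect_identical(cohort(rows)$nuclear$sibship_size, 3L)
})

test_that("phenotype_mask applies the category definitions and conserves counts", {
  rows <- rbind(nuclear_family_rows("F1", 6))
  ids <- sprintf("F1_C%d", 1:6)
  rows$phenotype[match(ids, rows$id)] <-
    c("myxedematous_moderate", "mixed", "neurological", "deaf_mute",
      "unaffected", "unknown")
  rows$alive[rows$id == "F1_C5"] <- FALSE
  coh <- cohort(rows)

  myx <- phenotype_mask(coh, "myxedematous")
  expect_identical(unname(myx[ids]),
                   c("affected", "affected", "control", "control",
                     "unphenotyped", "unphenotyped"))
  neu <- phenotype_mask(coh, "neurological")
  expect_identical(unname(neu[c("F1_C1", "F1_C3", "F1_C4")]),
                   c("control", "affected", "affected"))
  comb <- phenotype_mask(coh, "combined")
  expect_identical(sum(comb == "affected"), 4L)

  for (cat in c("combined", "myxedematous", "neurological")) {
    m <- phenotype_mask(coh, cat)
    expect_identical(length(m), nrow(coh$individuals))
    expect_identical(sum(m == "affected") + sum(m == "control") +
                       sum(m == "unphenotyped"), nrow(coh$individuals))
  }
})

test_that("family_counts includes parents and excludes the unphenotyped", {
  rows <- rbind(nuclear_family_rows("F1", 5, k = 2), nuclear_family_rows("F2", 3))
  rows$alive[rows$id == "F1_C5"] <- FALSE
  rows$phenotype[rows$id == "F1_C5"] <- "unknown"
  fc <- family_counts(cohort(rows), "combined")
  expect_identical(fc$n_phenotyped, c(6L, 5L))
  expect_identical(fc$k_affected, c(2L, 0L))
})
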