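writeModalityFile <- function(df, ext = "tsv") {
  path <- tempfile(fileext = paste0(".", ext))
  sep <- if (ext == "csv") "," else "\t"
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  path
}

baseTable <- function(regions, values) {
  cbind(data.frame(subject_id = c("s1", "s2", "s3"),
                   group = c("CN", "CN", "bvFTD"),
                   age = c(60, 65, 70), sex = c("M", "F", "M"),
                   education = c(12, 14, 16)),
        setNames(as.data.frame(values), regions))
}

test_that("smallest valid two-modality cohort reads with canonical shape", {
  atl <- toyAtlas(4)
  v1 <- matrix(seq(1, 12) / 10, 3, 4)
  v2 <- matrix(seq(13, 24) / 10, 3, 4)
  p1 <- writeModalityFile(baseTable(regions(atl), v1))
  p2 <- writeModalityFile(baseTable(regions(atl), v2), ext = "csv")
  co <- readCohort(c(CTH = p1, FDG = p2), atl)
  expect_s4_class(co, "CohortTable")
  expect_identical(modalities(co), c("CTH", "FDG"))
  expect_identical(dim(co), c(4L, 3L))
  expect_equal(unname(assay(co, "CTH")), t(v1))
  # textual sex recoded M -> 1, F -> 0
  expect_equal(SummarizedExperiment::colData(co)$sex, c(1, 0, 1))
})

test_that("shuffled region columns are restored to atlas order", {
  atl <- toyAtlas(4)
  v <- matrix(rnorm(12), 3, 4)
  tab <- baseTable(regions(atl), v)
  shuf <- tab[, c(1:5, 8, 6, 9, 7)]
  co1 <- readCohort(c(CTH = writeModalityFile(tab)), atl)
  co2 <- readCohort(c(CTH = writeModalityFile(shuf)), atl)
  expect_equal(assay(co1, "CTH"), assay(co2, "CTH"))
  expect_identical(rownames(co2), regions(atl))
})

test_that("validation errors name the offending column or subject", {
  atl <- roiAtlas("dk-ish", c("lh-entorhinal", "lh-fusiform", "rh-insula"))
  v <- matrix(rnorm(9), 3, 3)
  tab <- baseTable(regions(atl), v)
  expect_error(readCohort(c(CTH = writeModalityFile(tab[, -6])), atl),
               "lh-entorhinal")
  tabDup <- tab; tabDup$subject_id <- c("s1", "s1", "s3")
  expect_error(readCohort(c(CTH = writeModalityFile(tabDup)), atl),
               "duplicate subject_id")
  tabBad <- tab; tabBad[["lh-fusiform"]] <- c("1.2", "x", "0.9")
  expect_error(readCohort(c(CTH = writeModalityFile(tabBad)), atl),
               "lh-fusiform|non-finite")
  # subject present in one modality only
  expect_error(
    readCohort(c(CTH = writeModalityFile(tab),
                 FDG = writeModalityFile(tab[c(1, 2), ])), atl),
    "subject set differs")
})

test_that("write/read round-trip reproduces all values bit-identically", {
  set.seed(41)
  co <- generateCohort(generatorConfig(nPerGroup = c(CN = 5, PPA = 4),
                                       nRegions = 6, seed = 8))$cohort
  paths <- c(CTH = tempfile(fileext = ".tsv"), FDG = tempfile(fileext = ".csv"))
  writeCohort(co, paths)
  back <- readCohort(paths, atlas(co))
  expect_identical(assay(back, "CTH"), assay(co, "CTH"))
  expect_identical(assay(back, "FDG"), assay(co, "FDG"))
  expect_identical(SummarizedExperiment::colData(back)$age,
                   SummarizedExperiment::colData(co)$age)
})

test_that("splitByGroup partitions and rejects unknown labels", {
  set.seed(1)
  co <- generateCohort(generatorConfig(nPerGroup = c(bvFTD = 5, PPA = 4),
                                       nRegions = 4, seed = 2))$cohort
  sp <- splitByGroup(co, c("bvFTD", "PPA"))
  expect_identical(vapply(sp, ncol, 0L), c(bvFTD = 5L, PPA = 4L))
  expect_identical(sum(vapply(sp, ncol, 0L)), ncol(co))
  one <- splitByGroup(co, "PPA")
  expect_identical(groups(one$PPA), "PPA")
  expect_error(splitByGroup(co, "AD"), "unknown group label")
})

test_that("bundled atlases have the documented sizes and unique regions", {
  dk <- dkAtlas(); dx <- destrieuxAtlas()
  expect_identical(nRegions(dk), 68L)
  expect_identical(nRegions(dx), 148L)
  expect_false(anyDuplicated(regions(dk)) > 0)
  expect_true("lh-entorhinal" %in% regions(dk))
  expect_setequal(unique(sub("-.*", "", regions(dk))), c("lh", "rh"))
})
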