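test_that("common DEG intersection handles overlap, disjoint and identical tables", {
  cfg <- synthConfig(23)
  ref <- sprintf("g%04d", 1:100)
  t1 <- DegTable(c(ref[1:30], ref[61:80], "only1"),
                 c(rep(3, 30), rep(-3, 20), 4), rep(0.01, 51))
  t2 <- DegTable(c(ref[11:40], ref[61:75]),
                 c(rep(3, 30), rep(-3, 15)), rep(0.01, 45))
  cd <- commonDegs(list(a = t1, b = t2))
  expect_identical(sort(members(cd$up)), sort(ref[11:30]))
  expect_identical(sort(members(cd$down)), sort(ref[61:75]))
  # disjoint tables
  d1 <- DegTable("x", 3, 0.01); d2 <- DegTable("y", 3, 0.01)
  disj <- commonDegs(list(d1, d2))
  expect_length(members(disj$up), 0L)
  # identical tables intersect to themselves
  same <- commonDegs(list(t1, t1))
  expect_identical(sort(members(same$up)), sort(c(ref[1:30], "only1")))
  expect_error(commonDegs(list(t1)), "at least 2")
})

test_that("direction conflicts are excluded from both common sets and logged", {
  t1 <- DegTable(c("g1", "g2"), c(3, 3), c(0.01, 0.01))
  t2 <- DegTable(c("g1", "g2"), c(-3, 3), c(0.01, 0.01))
  expect_message(cd <- commonDegs(list(t1, t2)), "excluded")
  expect_identical(cd$conflicted, "g1")
  expect_identical(members(cd$up), "g2")
  expect_length(members(cd$down), 0L)
})

test_that("overlap statistics reproduce the reference-percentage convention", {
  ref <- sprintf("h%03d", 1:116)
  ov <- overlapStats(ref[1:42], ref[43:54], ref)
  expect_equal(ov$up_count, 42L)
  expect_equal(ov$up_pct, 36.21)
  expect_equal(ov$down_count, 12L)
  expect_equal(ov$down_pct, 10.34)
  expect_equal(overlapStats(character(), character(), ref)$up_pct, 0)
  expect_equal(overlapStats(c(ref, "extra"), character(), ref)$up_pct, 100)
  expect_error(overlapStats("a", "b", character()), "non-empty")
  # single-gene reference: percentages are 0 or 100
  expect_true(overlapStats("z", character(), "z")$up_pct == 100)
  expect_true(overlapStats("q", character(), "z")$up_pct == 0)
  # pure set semantics: relabeling genes leaves percentages unchanged
  relabel <- setNames(sprintf("X%03d", seq_along(ref)), ref)
  ov2 <- overlapStats(unname(relabel[ref[1:42]]), unname(relabel[ref[43:54]]),
                      unname(relabel))
  expect_equal(ov2$up_pct, ov$up_pct)
})

test_that("stage composition reports per-stage counts and percentages", {
  sets <- StageSets(myoStages(),
                    list(sprintf("a%04d", 1:4252), sprintf("b%03d", 1:158),
                         sprintf("c%03d", 1:266), sprintf("d%03d", 1:198),
                         sprintf("e%03d", 1:330)))
  up <- c(sprintf("d%03d", 1:113), sprintf("e%03d", 1:79))
  comp <- stageComposition(up, sets)
  expect_equal(comp$pct[comp$stage == "MYOG"], 57.07)
  expect_equal(comp$pct[comp$stage == "TUB"], 23.94)
  expect_equal(comp$count[comp$stage == "OCT4"], 0L)
  empty <- stageComposition(character(), sets)
  expect_true(all(empty$count == 0L))
  expect_true(all(empty$pct == 0))
  # empty stage set: count 0, undefined percentage
  withEmpty <- StageSets(c("s1", "s2"), list(c("x"), character()))
  ce <- stageComposition("x", withEmpty)
  expect_equal(ce$count[2], 0L)
  expect_true(is.na(ce$pct[2]))
})

test_that("signature and maintenance coverage count reference intersections", {
  signature <- c("DUPD1", "KLHL38", "METTL11B", "MYH6", "MYL7", "OR5H2",
                 "OR6C70", "OR9Q1")
  expressed <- c(signature[1:5], "GAPDH")
  expect_equal(signatureCoverage(expressed, signature), 5L)
  expect_equal(signatureCoverage("GAPDH", signature), 0L)
  expect_equal(signatureCoverage(c(signature, "x"), signature), 8L)

  maint <- sprintf("m%02d", 1:71)
  mc <- maintenanceCoverage(maint[1:61], maint)
  expect_equal(mc$count, 61L)
  expect_equal(mc$pct, 86)
  expect_equal(maintenanceCoverage(character(), maint)$pct, 0)
  expect_equal(maintenanceCoverage(maint, maint)$pct, 100)
  expect_error(maintenanceCoverage("x", character()), "non-empty")
})

test_that("percentage rounding matches the exact integer-arithmetic oracle", {
  for (n in c(1:40, 71, 116, 198, 330, 500)) {
    k <- 0:n
    expect_equal(roundHalfAway(100 * k / n, 2), bruteRoundPct(k, n, 2),
                 label = sprintf("n = %d, 2 decimals", n))
    expect_equal(roundHalfAway(100 * k / n, 0), bruteRoundPct(k, n, 0),
                 label = sprintf("n = %d, 0 decimals", n))
  }
  # away-from-zero on negatives
  expect_equal(roundHalfAway(-2.5, 0), -3)
  expect_equal(roundHalfAway(-0.125, 2), -0.13)
})

makeReportConfig <- function(dir, nCellTypes = 3L) {
  cfg <- synthConfig(29)
  grn <- sprintf("HUB%03d", 1:116)
  signature <- c("DUPD1", "KLHL38", "METTL11B", "MYH6", "MYL7", "OR5H2",
                 "OR6C70", "OR9Q1")
  prof <- genStageProfiles(myoStages(), c(40, 10, 8, 6, 12), c(5, 2, 0, 0, 0),
                           nDistractors = 30, cfg = cfg)
  ss <- stageOnsetSets(prof)
  maint <- maintenanceGenes(prof)$genes
  writeGmt(GeneSet("grn", grn), file.path(dir, "grn.gmt"))
  writeGmt(GeneSet("signature", signature), file.path(dir, "signature.gmt"))
  writeGmt(lapply(myoStages(), function(s)
    GeneSet(s, stageSetList(ss)[[s]], "stage onset set")),
    file.path(dir, "stage_sets.gmt"))
  writeGmt(maint, file.path(dir, "maintenance.gmt"))
  writeGmt(GeneSet("smt", members(maint)[1:6]), file.path(dir, "smt.gmt"))
  tables <- list()
  for (i in seq_len(nCellTypes)) {
    ct <- c("hFB", "hADMSC", "hDFSC")[i]
    extraUp <- c(stageSetList(ss)$MYOG[1:3], members(maint)[1:4],
                 signature[seq_len(3 + i)])
    tab <- rbind(genDegTable(grn, 42, 12, 50, synthConfig(29 + i)),
                 DegTable(extraUp, rep(4, length(extraUp)),
                          rep(0.001, length(extraUp))))
    path <- file.path(dir, paste0(ct, ".tsv"))
    writeDegTable(tab, path)
    tables[[ct]] <- path
  }
  list(inputs = list(deg_tables = tables, fold_scale = "linear",
                     grn = file.path(dir, "grn.gmt"),
                     signature = file.path(dir, "signature.gmt"),
                     stage_sets = file.path(dir, "stage_sets.gmt"),
                     maintenance = file.path(dir, "maintenance.gmt"),
                     smt_transcriptome = file.path(dir, "smt.gmt")),
       thresholds = list(p_max = 0.05, min_fold = 2),
       scoring = list(pct_decimals = 2, maintenance_pct_decimals = 0))
}

test_that("the maturity report reproduces planted ground truth end to end", {
  dir <- withr::local_tempdir()
  config <- makeReportConfig(dir)
  report <- buildMaturityReport(config)
  expect_s4_class(report, "MaturityReport")
  expect_identical(names(report@perCellType), c("hFB", "hADMSC", "hDFSC"))
  for (i in 1:3) {
    p <- report@perCellType[[i]]
    expect_equal(p$grn_up_count, 42L)
    expect_equal(p$grn_up_pct, 36.21)
    expect_equal(p$grn_down_count, 12L)
    expect_equal(p$signature_expressed_count, 3L + i)
  }
  expect_equal(report@params$smt_maintenance_count, 6L)
  expect_equal(report@params$smt_maintenance_pct,
               bruteRoundPct(6, 7, 0))
  # YAML config path behaves identically
  yamlPath <- file.path(dir, "config.yaml")
  yaml::write_yaml(config, yamlPath)
  report2 <- buildMaturityReport(yamlPath)
  expect_equal(report2@perCellType, report@perCellType)
})

test_that("report files are byte-identical across regenerations", {
  dir <- withr::local_tempdir()
  config <- makeReportConfig(dir)
  report <- buildMaturityReport(config)
  j1 <- file.path(dir, "r1.json"); j2 <- file.path(dir, "r2.json")
  t1 <- file.path(dir, "r1.tsv"); t2 <- file.path(dir, "r2.tsv")
  writeMaturityReport(report, j1, t1)
  writeMaturityReport(buildMaturityReport(config), j2, t2)
  expect_identical(readLines(j1), readLines(j2))
  expect_identical(readLines(t1), readLines(t2))
  tsv <- read.delim(t1)
  expect_true(all(c("cell_type", "metric", "value") %in% names(tsv)))
})

test_that("a single-cell-type report omits the common-DEG section", {
  dir <- withr::local_tempdir()
  config <- makeReportConfig(dir, nCellTypes = 1L)
  report <- buildMaturityReport(config)
  expect_length(report@common, 0L)
  expect_length(report@perCellType, 1L)
  expect_error(buildMaturityReport(list(inputs = list())), "missing input")
})
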