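writeTsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("IC50 records aggregate into active/inactive/ambiguous labels", {
  path <- writeTsv(data.frame(
    chemical_id = c("c1", "c1", "c2", "c2", "c3"),
    protein_id  = c("p1", "p1", "p1", "p1", "p2"),
    ic50_value  = c(5, 2, 5, 50, 20),
    ic50_unit   = "uM"))
  tab <- readInteractions(path, ic50Threshold = 10)
  p <- interactionPairs(tab)
  lab <- setNames(p$label, paste(p$chemical, p$protein))
  expect_identical(lab[["c1 p1"]], "active")     # 5 and 2 both <= 10
  expect_identical(lab[["c2 p1"]], "ambiguous")  # records in both ranges
  expect_identical(lab[["c3 p2"]], "inactive")
  expect_equal(nrow(positivePairs(tab)), 1L)
})

test_that("unit conversion handles molar prefixes and mass units", {
  expect_equal(ic50ToMicromolar(1000, 100), 10)
  expect_equal(ic50ToMicromolar(0, 42), 0)
  expect_equal(ic50ToMicromolar(250, 500), 0.5)
  expect_error(ic50ToMicromolar(5, 0), "molecularWeight")
  # linearity in value, inverse-linearity in molecular weight
  set.seed(11)
  v <- runif(20, 1, 1000); mw <- runif(20, 10, 900); a <- runif(20, 0.1, 5)
  expect_equal(ic50ToMicromolar(a * v, mw), a * ic50ToMicromolar(v, mw))
  expect_equal(ic50ToMicromolar(v, a * mw), ic50ToMicromolar(v, mw) / a)
  # a 1000 ug/L record of a 100 g/mol compound is 10 uM: at threshold
  path <- writeTsv(data.frame(
    chemical_id = "c1", protein_id = "p1",
    ic50_value = 1000, ic50_unit = "ug/L", molecular_weight = 100))
  expect_identical(interactionPairs(readInteractions(path))$label, "active")
  path2 <- writeTsv(data.frame(
    chemical_id = "c1", protein_id = "p1",
    ic50_value = 5000, ic50_unit = "nM"))
  expect_identical(interactionPairs(readInteractions(path2))$label,
                   "active")  # 5 uM
})

test_that("reader rejects malformed rows and unknown units by line", {
  bad <- writeTsv(data.frame(chemical_id = "c1", protein_id = "p1",
                             ic50_value = "abc", ic50_unit = "uM"))
  expect_error(readInteractions(bad), "line 2")
  badUnit <- writeTsv(data.frame(chemical_id = "c1", protein_id = "p1",
                                 ic50_value = 1, ic50_unit = "furlongs"))
  expect_error(readInteractions(badUnit), "unknown IC50 unit")
})

test_that("explicit labels pass through and empty input yields empty table", {
  path <- writeTsv(data.frame(chemical_id = c("c1", "c2"),
                              protein_id = c("p1", "p1"),
                              label = c("active", "ambiguous")))
  tab <- readInteractions(path)
  expect_setequal(interactionPairs(tab)$label, c("active", "ambiguous"))
  empty <- writeTsv(data.frame(chemical_id = character(0),
                               protein_id = character(0),
                               label = character(0)))
  tab0 <- readInteractions(empty)
  expect_equal(nrow(interactionPairs(tab0)), 0L)
})

test_that("label aggregation is order-independent", {
  set.seed(5)
  base <- data.frame(
    chemical_id = sample(sprintf("c%d", 1:6), 40, replace = TRUE),
    protein_id = sample(sprintf("p%d", 1:5), 40, replace = TRUE),
    ic50_value = runif(40, 0.1, 100), ic50_unit = "uM")
  t1 <- readInteractions(writeTsv(base))
  shuf <- base[sample(nrow(base)), ]
  t2 <- readInteractions(writeTsv(shuf))
  key <- function(tt) {
    p <- interactionPairs(tt)
    p <- p[order(p$chemical, p$protein), ]
    paste(p$chemical, p$protein, p$label)
  }
  expect_identical(key(t1), key(t2))
})

test_that("fingerprint hex encoding decodes big-endian and round-trips", {
  path <- writeTsv(data.frame(id = c("c1", "c2", "c3"), nbits = 8,
                              hex = c("FF", "00", "A0")))
  fps <- readFingerprints(path)
  expect_identical(fps@bits[[1]], 0:7)
  expect_identical(fps@bits[[2]], integer(0))
  expect_identical(fps@bits[[3]], c(0L, 2L))  # A0 = 1010 0000
  # random round trip through the writer
  set.seed(9)
  rnd <- fingerprintSet(sprintf("x%d", 1:10),
                        lapply(1:10, function(i) sample(0:63, sample(0:20, 1))),
                        nbits = 64)
  p2 <- tempfile(fileext = ".tsv")
  writeFingerprints(rnd, p2)
  back <- readFingerprints(p2)
  expect_identical(back@bits, rnd@bits)
  expect_identical(back@ids, rnd@ids)
  # inconsistent hex length is a format error
  bad <- writeTsv(data.frame(id = "c1", nbits = 16, hex = "FF"))
  expect_error(readFingerprints(bad), "inconsistent")
})

test_that("BLAST tabular parsing filters by e-value and keeps max bitscore", {
  row12 <- function(q, s, ev, bit)
    paste(q, s, "90.0", "100", "5", "1", "1", "100", "1", "100", ev, bit,
          sep = "\t")
  path <- tempfile()
  writeLines(c(row12("q", "s", "1e-7", "50"),
               row12("q", "t", "1e-3", "80"),
               row12("q", "s", "1e-9", "60"),
               row12("q", "s", "1e-8", "40")), path)
  hits <- readBlastTabular(path, evalueThreshold = 1e-5)
  expect_equal(nrow(hits), 1L)          # q-t discarded, q-s deduplicated
  expect_equal(hits$bitscore, 60)       # max of 50, 60, 40
  short <- tempfile()
  writeLines("q\ts\tonly-three", short)
  expect_error(readBlastTabular(short), "12")
})

test_that("prediction files are deterministic and round-trip", {
  preds <- data.frame(chemical = c("c2", "c1", "c1"),
                      protein = c("p1", "p3", "p2"),
                      score = c(0.5, 0.9, 0.25),
                      rank = c(1L, 1L, 2L))
  f1 <- tempfile(); f2 <- tempfile()
  writePredictions(preds, f1)
  writePredictions(preds, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  back <- readPredictions(f1)
  expect_equal(nrow(back), 3L)
  expect_equal(back$chemical, c("c1", "c1", "c2"))  # sorted by chem, rank
  expect_equal(back$score[back$protein == "p3"], 0.9)
  empty <- tempfile()
  writePredictions(preds[0, ], empty)
  expect_equal(length(readLines(empty)), 1L)  # header only
})

test_that("cold-start chemicals can live in the vocabulary without pairs", {
  tab <- interactionTable(
    data.frame(chemical = "c1", protein = "p1", label = "active"),
    chemIds = c("c1", "c2"), protIds = c("p1", "p2"))
  expect_equal(nChemicals(tab), 2L)
  expect_equal(sum(positiveMatrix(tab)[2, ]), 0)
})
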