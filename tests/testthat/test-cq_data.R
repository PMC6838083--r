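test_that("long-dialect parsing counts records and normalises undetected markers", {
  path <- write_long_csv(
    sample = rep(c("S1", "S2"), each = 6),
    group = rep(c("ctl", "pat"), each = 6),
    gene = rep(rep(c("GAPDH", "ACTB"), each = 3), 2),
    replicate = rep(1:3, 4),
    cq = c(20.1, 20.2, 20.3, 22.0, 22.1, 21.9,
           "Undetermined", "19.8", "19.9", "nd", "NA", "25.0"))
  tab <- read_cq_table(path, "long")
  expect_s3_class(tab, "raw_cq_table")
  expect_equal(nrow(tab), 12L)
  expect_equal(attr(tab, "gene_levels"), c("GAPDH", "ACTB"))
  expect_equal(sum(is.na(tab$cq)), 3L)  # Undetermined, nd, NA
})

test_that("malformed long tables are rejected with an informative error", {
  dup <- write_long_csv(sample = c("S1", "S1"), group = c("g", "g"),
                        gene = c("GAPDH", "GAPDH"), replicate = c(1, 1),
                        cq = c(20, 21))
  expect_error(read_cq_table(dup, "long"), "S1, GAPDH, 1",
               class = "cliqueref_input_error")
  bad_col <- tempfile(fileext = ".csv")
  writeLines(c("sample,group,gene,replicate,cq,extra",
               "S1,g,GAPDH,1,20,x"), bad_col)
  expect_error(read_cq_table(bad_col, "long"), "columns",
               class = "cliqueref_input_error")
  bad_cq <- write_long_csv("S1", "g", "GAPDH", 1, "twenty")
  expect_error(read_cq_table(bad_cq, "long"), "twenty",
               class = "cliqueref_input_error")
  two_groups <- write_long_csv(c("S1", "S1"), c("g1", "g2"),
                               c("GAPDH", "ACTB"), c(1, 1), c(20, 21))
  expect_error(read_cq_table(two_groups, "long"), "more than one group",
               class = "cliqueref_input_error")
})

test_that("wide-dialect parsing returns a Cq matrix and rejects duplicates", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("sample,group,GAPDH,ACTB",
               "S1,ctl,20.1,22.3",
               "S2,pat,Undetermined,21.9"), path)
  m <- read_cq_table(path, "wide")
  expect_s3_class(m, "cq_matrix")
  expect_equal(dim(m$cq), c(2L, 2L))
  expect_true(is.na(m$cq["S2", "GAPDH"]))
  expect_equal(unname(m$groups), c("ctl", "pat"))
  dup_gene <- tempfile(fileext = ".csv")
  writeLines(c("sample,group,GAPDH,GAPDH", "S1,ctl,20,21"), dup_gene)
  expect_error(read_cq_table(dup_gene, "wide"), "duplicated gene",
               class = "cliqueref_input_error")
})

test_that("failure rule: any late or undetected replicate fails the triplicate", {
  tab <- triplicate_table(list(
    "S1|A" = c(31.9, 31.5, 31.2),
    "S1|B" = c(33.1, 28.0, 28.2),
    "S1|C" = c(NA, 20.0, 20.1)))
  flags <- flag_failures(tab)
  expect_equal(stats::setNames(flags$failed, flags$gene),
               c(A = FALSE, B = TRUE, C = TRUE))
  # failure flagging happens before outlier elimination: the 33.1 replicate
  # is not rescued by dropping it
  m <- average_triplicates(tab)
  expect_true(is.na(m$cq["S1", "B"]))
  expect_false(is.na(m$cq["S1", "A"]))
})

test_that("triplicate averaging drops exactly one outlier above the SD threshold", {
  tab <- triplicate_table(list(
    "S1|A" = c(20.0, 20.1, 20.2),   # SD 0.1: untouched
    "S1|B" = c(20.0, 20.1, 22.0),   # outlier dropped
    "S1|C" = c(20.0, 21.0, 22.0)))  # SD 1.0, tied deviations
  m <- average_triplicates(tab)
  qc <- m$qc
  rownames(qc) <- qc$gene
  expect_equal(m$cq["S1", "A"], 20.1)
  expect_true(is.na(qc["A", "dropped_replicate"]))
  expect_equal(m$cq["S1", "B"], 20.05)
  expect_equal(qc["B", "dropped_replicate"], 3L)
  expect_equal(qc["B", "n_used"], 2L)
  # deviations tie between replicates 1 and 3: the later-indexed one goes
  expect_equal(m$cq["S1", "C"], 20.5)
  expect_equal(qc["C", "dropped_replicate"], 3L)
  expect_equal(qc["C", "raw_sd"], 1.0)
})

test_that("averaging is idempotent on an already-averaged table", {
  set.seed(71)
  tab <- triplicate_table(list(
    "S1|A" = rnorm(3, 20, 0.3), "S1|B" = rnorm(3, 24, 0.3),
    "S2|A" = rnorm(3, 20, 0.3), "S2|B" = c(25, 25.1, 27)))
  m1 <- average_triplicates(tab)
  redo <- raw_cq_table(rep(rownames(m1$cq), 2), "A",
                       rep(colnames(m1$cq), each = 2),
                       rep(1L, 4), as.vector(m1$cq))
  m2 <- average_triplicates(redo)
  expect_equal(m2$cq, m1$cq)
  expect_true(all(is.na(m2$qc$dropped_replicate)))
})

test_that("outlier elimination never increases the retained SD and keeps the mean near the median", {
  set.seed(72)
  for (i in 1:200) {
    v <- rnorm(3, 25, runif(1, 0.05, 2))
    tab <- triplicate_table(list("S1|A" = v))
    m <- average_triplicates(tab, max_cq = Inf)
    qc <- m$qc
    if (!is.na(qc$dropped_replicate)) {
      kept <- v[-qc$dropped_replicate]
      expect_lte(stats::sd(kept), stats::sd(v))
    }
    expect_lte(abs(m$cq[1, 1] - stats::median(v)), max(v) - min(v) + 1e-12)
    # permutation invariance of the emitted mean (tie-break aside, values
    # drawn continuously so ties have probability zero)
    perm <- sample(3)
    tab_p <- triplicate_table(list("S1|A" = v[perm]))
    expect_equal(average_triplicates(tab_p, max_cq = Inf)$cq[1, 1],
                 m$cq[1, 1])
  }
})

test_that("variability summary matches closed-form SDs and flags undefined groups", {
  tab <- raw_cq_table(
    sample = rep(c("S1", "S2", "S3"), each = 3),
    group = rep(c("ctl", "ctl", "pat"), each = 3),
    gene = "A", replicate = rep(1:3, 3),
    cq = c(10, 10, 10, 16.5, 16.6, 16.7, 20, 20.2, 20.4))
  m <- average_triplicates(tab)
  vs <- variability_summary(tab, m)
  expect_equal(vs$intra_assay$sd[vs$intra_assay$sample == "S1"], 0)
  # two-point SD |a - b| / sqrt(2) for the control group averages
  ctl <- vs$inter_individual
  expect_equal(ctl$sd[ctl$group == "ctl"],
               abs(10 - 16.6) / sqrt(2))
  # a single patient sample cannot yield an SD
  expect_true(is.na(ctl$sd[ctl$group == "pat"]))
  expect_equal(ctl$n[ctl$group == "pat"], 1L)
})

test_that("QC report and matrix round-trip through their file formats", {
  tab <- triplicate_table(list(
    "S1|A|ctl" = c(20, 20.1, 20.2), "S1|B|ctl" = c(NA, 30, 30.1),
    "S2|A|pat" = c(21, 21.1, 23), "S2|B|pat" = c(28, 28.1, 28.2)))
  m <- average_triplicates(tab)
  qc_path <- tempfile(fileext = ".tsv")
  write_qc_report(m, qc_path)
  qc <- utils::read.delim(qc_path)
  expect_equal(nrow(qc), 4L)
  expect_equal(sum(qc$failed), 1L)
  mat_path <- tempfile(fileext = ".csv")
  write_cq_matrix(m, mat_path)
  back <- read_cq_table(mat_path, "wide")
  expect_equal(back$cq, m$cq, tolerance = 1e-6)
  expect_equal(back$groups, m$groups)
})
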