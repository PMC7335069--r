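make_donors <- function(n_donors, nr = 6, ng = 8, seed = 1) {
  withr::with_seed(seed, {
    purrr::map(seq_len(n_donors), function(d) {
      m <- matrix(rnorm(nr * ng), nr, ng,
                  dimnames = list(sprintf("r%d", 1:nr), sprintf("g%d", 1:ng)))
      m
    })
  })
}

test_that("donor aggregation is median-then-z", {
  donors <- make_donors(5)
  atl <- aggregate_donor_expression(donors)
  # oracle: elementwise median via apply, then per-gene scale()
  arr <- array(unlist(donors), dim = c(6, 8, 5))
  med <- apply(arr, c(1, 2), median)
  oracle <- scale(med)
  expect_lt(max(abs(atl$expr - oracle)), 1e-12)
  # z invariants
  expect_lt(max(abs(colMeans(atl$expr))), 1e-9)
  expect_lt(max(abs(apply(atl$expr, 2, sd) - 1)), 1e-9)
})

test_that("aggregation of one donor, or identical donors, is the z of that donor", {
  donors <- make_donors(1)
  one <- aggregate_donor_expression(donors)
  expect_lt(max(abs(one$expr - scale(donors[[1]]))), 1e-12)
  same <- aggregate_donor_expression(donors[c(1, 1, 1)])
  expect_equal(same$expr, one$expr)
})

test_that("the elementwise median honours the definition cell by cell", {
  d <- lapply(c(1, 2, 9), function(v) matrix(v, 2, 2, dimnames = list(c("a", "b"), c("x", "y"))))
  med <- neurovuln:::elementwise_median(d)
  expect_true(all(med == 2))
})

test_that("misaligned donors are rejected", {
  donors <- make_donors(3)
  rownames(donors[[2]]) <- rev(rownames(donors[[2]]))
  expect_error(aggregate_donor_expression(donors), class = "nv_alignment_error")
})

test_that("brain-expressed filtering subsets columns without re-z-scoring", {
  atlas <- atlas_fix$atlas
  ann <- atlas$annotations
  filt <- filter_brain_expressed(atlas)
  expect_equal(ncol(filt$expr), sum(ann$brain_expressed))
  keep1 <- ann$gene[ann$brain_expressed][1]
  expect_equal(filt$expr[, keep1], atlas$expr[, keep1])
  # all flags true -> identity
  atlas2 <- atlas
  atlas2$annotations$brain_expressed <- TRUE
  expect_equal(filter_brain_expressed(atlas2)$expr, atlas$expr)
})

test_that("CNV gene sets derive from chromosomes, intervals and breakpoints", {
  ann <- tibble::tibble(
    gene = sprintf("g%d", 1:8),
    chromosome = c("11", "11", "11", "11", "21", "21", "X", "X"),
    start = c(15, 25, 90, 130, 10, 20, 5, 6),
    end = c(18, 30, 95, 140, 12, 25, 7, 8)
  )
  # breakpoint medians: proximal {10,20,30} -> 20; distal {100,120,140} -> 120
  gs <- derive_cnv_gene_set(ann, "11", proximal = c(10, 20, 30),
                            distal = c(100, 120, 140))
  expect_setequal(gs$members, c("g2", "g3"))
  expect_equal(gs$provenance, "interval")
  # whole chromosome
  expect_setequal(derive_cnv_gene_set(ann, "21")$members, c("g5", "g6"))
  # widening the interval never removes members
  wider <- derive_cnv_gene_set(ann, "11", start = 10, end = 150)
  expect_true(all(gs$members %in% wider$members))
  expect_error(derive_cnv_gene_set(ann, "11", start = 1, end = 2),
               class = "nv_empty_gene_set")
})

test_that("the planted CNV interval is recovered exactly from the manifest", {
  man <- atlas_fix$manifest
  ann <- atlas_fix$atlas$annotations
  gs <- derive_cnv_gene_set(ann, man$cnv$chromosome,
                            start = man$cnv$interval["start"],
                            end = man$cnv$interval["end"])
  expect_setequal(gs$members, man$cnv$genes)
})

test_that("leave-one-donor-out atlases equal aggregation of the complement", {
  donors <- make_donors(4, seed = 9)
  lodo <- leave_one_donor_out_atlases(donors)
  expect_length(lodo, 4)
  for (i in 1:4) {
    expect_equal(lodo[[i]]$expr,
                 aggregate_donor_expression(donors[-i])$expr)
  }
  same <- leave_one_donor_out_atlases(make_donors(1)[c(1, 1, 1)])
  expect_equal(same[[1]]$expr, same[[2]]$expr)
  expect_error(leave_one_donor_out_atlases(donors[1]), class = "nv_bad_argument")
})

test_that("planted atlas realizes its coupling target approximately", {
  man <- atlas_fix$manifest
  atlas <- atlas_fix$atlas
  f1 <- man$factors[rownames(atlas$expr), 1]
  r <- cor(rowMeans(atlas$expr[, man$cnv$genes]), f1)
  expect_gt(r, 0.4)   # small fixture: loose sanity bound, exact MC check in acceptance
})

test_that("gene sets deduplicate members with a warning and reject empties", {
  expect_warning(gs <- gene_set("s", c("a", "b", "a")), "duplicate")
  expect_equal(gs$members, c("a", "b"))
  expect_error(gene_set("s", character(0)), class = "nv_empty_gene_set")
})
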