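# brute-force reimplementation of the substring rule, used as oracle
brute_substring <- function(genes, tokens) {
  keep <- logical(length(genes))
  for (i in seq_along(genes)) {
    hit <- FALSE
    for (tok in tokens) {
      for (s in seq_len(nchar(genes[i]) - nchar(tok) + 1)) {
        if (substr(genes[i], s, s + nchar(tok) - 1) == tok) hit <- TRUE
      }
    }
    keep[i] <- !hit
  }
  genes[keep]
}

test_that("substring blacklist removes matching symbols with a recorded reason", {
  r <- substring_filter(c("Rpl13", "Cd74"))
  expect_equal(r$kept, "Cd74")
  expect_equal(r$removed$gene, "Rpl13")
  expect_equal(r$removed$reason, "Rpl")

  r <- substring_filter(toy_genes)
  expect_setequal(r$kept, c("Cd74", "Saa3", "Lyve1", "Mrc1", "H2-Aa", "Folr2"))
  expect_equal(length(r$kept), 6)
  expect_equal(sort(r$kept),
               sort(brute_substring(toy_genes, default_substring_blacklist())))
  # partition: kept and removed are disjoint and rebuild the input
  expect_setequal(c(r$kept, r$removed$gene), toy_genes)
  expect_length(intersect(r$kept, r$removed$gene), 0)
})

test_that("matching is case sensitive and anywhere in the symbol", {
  r <- substring_filter(c("2310022B05Rik", "RIKEN1", "Snca", "Dnajb1"))
  expect_equal(sort(r$removed$gene), c("2310022B05Rik", "Dnajb1", "Snca"))
  expect_equal(r$kept, "RIKEN1")  # "Rik" does not match upper case "RIK"
})

test_that("empty blacklist is the identity with a warning", {
  expect_warning(r <- substring_filter(c("Rpl13"), character()), "identity")
  expect_equal(r$kept, "Rpl13")
})

test_that("fraction rule removes genes lowly expressed in enough samples", {
  m <- rbind(g1 = c(0, 2, 3, 50),    # 3/4 samples below 10 -> removed
             g2 = c(12, 12, 0, 0))   # 2/4 below 10 -> kept
  colnames(m) <- paste0("s", 1:4)
  r <- low_expression_filter(m, "fraction_rule")
  expect_equal(r$removed, "g1")
  expect_equal(rownames(r$kept), "g2")
  expect_error(low_expression_filter(m, "fraction_rule", sample_fraction = 1.5),
               "\\(0, 1\\]")
  # row-sum reading removes on total counts instead
  r <- low_expression_filter(m, "fraction_rule", row_sum = TRUE,
                             count_threshold = 30)
  expect_equal(r$removed, "g2")
})

test_that("total rule uses a strict inequality against half the sample count", {
  m <- rbind(gA = c(1, 1, 0, 0, 0, 0),    # total 2 < 3 -> removed
             gB = c(1, 1, 1, 0, 0, 0))    # total 3, not < 3 -> kept
  colnames(m) <- paste0("s", 1:6)
  r <- low_expression_filter(m, "total_rule")
  expect_equal(r$removed, "gA")
  expect_equal(rownames(r$kept), "gB")
})

test_that("full filter spec applies stages in order with an exhaustive audit", {
  genes <- c(toy_genes, "Ps1", "Linc1", "Actb", "Ribo1", "Oxp1", "Hexb",
             "Sparc", "P2ry12")
  set.seed(4)
  m <- matrix(rpois(length(genes) * 4, 40), ncol = 4,
              dimnames = list(genes, paste0("s", 1:4)))
  m["Hexb", ] <- c(0, 1, 2, 50)  # trips the fraction rule
  biotypes <- c(Ps1 = "pseudogene", Linc1 = "lincRNA", Actb = "protein_coding")
  spec <- filter_spec(pathway_gene_sets = list(ribosome = c("Ribo1", "NotHere"),
                                               oxphos = "Oxp1"),
                      biotype_blacklist = c("pseudogene", "lincRNA"),
                      low_expression_rule = "fraction_rule")
  expect_warning(r <- apply_filter_spec(m, spec, biotypes),
                 "not in the matrix")

  # brute-force oracle for the survivor set
  surv <- genes
  surv <- setdiff(surv, c("Ribo1", "Oxp1"))
  surv <- setdiff(surv, c("Ps1", "Linc1"))
  surv <- brute_substring(surv, default_substring_blacklist())
  surv <- setdiff(surv, "Hexb")
  expect_setequal(rownames(r$counts), surv)

  # audit covers exactly the removed genes, once each
  expect_setequal(r$audit$gene, setdiff(genes, surv))
  expect_false(anyDuplicated(r$audit$gene) > 0)
  expect_setequal(unique(r$audit$stage),
                  c("pathway", "biotype", "substring", "low_expression"))

  # idempotence: reapplying the same spec removes nothing further
  # (the absent-pathway-gene warning fires again by design)
  r2 <- suppressWarnings(apply_filter_spec(r$counts, spec, biotypes))
  expect_identical(r2$counts, r$counts)
  expect_equal(nrow(r2$audit), 0)
})

test_that("an empty spec is the identity filter", {
  m <- matrix(1:6, 2, dimnames = list(c("Rpl13", "Cd74"), paste0("s", 1:3)))
  spec <- filter_spec(substring_blacklist = character(),
                      low_expression_rule = "none")
  r <- apply_filter_spec(m, spec)
  expect_identical(r$counts, m)
  expect_equal(nrow(r$audit), 0)
})
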