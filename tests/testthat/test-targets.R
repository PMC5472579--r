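# TargetScan-style parsing, name normalization, target mapping and the
# multiplicity / coverage statistics.

write_toy_db <- function(lines, header) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(c(header, lines), path)
  path
}

test_that("both file dialects load with identical records", {
  gen <- write_toy_db(c("hsa-miR-1-3p\tG1\tT1\t-0.2",
                        "hsa-miR-1-3p\tG2\tT2\t-0.1",
                        "hsa-miR-2-5p\tG1\tT1\t-0.3"),
                      "mir\tgene_symbol\ttranscript_id\tcontext_score")
  ts <- write_toy_db(
    c("G1\tT1\thsa-miR-1-3p\t-0.2\textra",
      "G2\tT2\thsa-miR-1-3p\t-0.1\textra",
      "G1\tT1\thsa-miR-2-5p\t-0.3\textra"),
    "Gene Symbol\tTranscript ID\tmiRNA\tcontext++ score\tnote")
  a <- load_targetscan(gen)
  b <- load_targetscan(ts)
  expect_equal(nrow(a$records), 3)
  expect_identical(a$records$mir_norm, b$records$mir_norm)
  expect_identical(a$records$gene_symbol, b$records$gene_symbol)
  expect_equal(a$records$context_score, b$records$context_score)
})

test_that("rows with empty scores are dropped and counted, duplicates deduplicated", {
  path <- write_toy_db(c("miR-1-3p\tG1\tT1\t-0.2",
                         "miR-1-3p\tG1\tT1\t",
                         "miR-9-5p\tG3\tT3\tNA"),
                       "mir\tgene_symbol\ttranscript_id\tcontext_score")
  db <- load_targetscan(path)
  expect_equal(nrow(db$records), 1)
  expect_equal(db$n_dropped, 2)
  # duplicate (mir, site_key) pairs collapse
  rec <- data.frame(mir = "miR-1-3p", gene_symbol = "G1",
                    transcript_id = "T1", context_score = -0.2,
                    site_key = "T1:s1")
  db2 <- target_db(rbind(rec, rec))
  expect_equal(nrow(db2$records), 1)
  expect_equal(db2$n_deduplicated, 1)
})

test_that("a missing required column is named in the error", {
  path <- write_toy_db("miR-1\tG1\t-0.2", "mir\tgene_symbol\tcontext_score")
  expect_error(load_targetscan(path), "transcript_id")
})

test_that("miR name normalization matches platform and database conventions", {
  expect_identical(normalize_mir_name("hsa-miR-30a-5p"), "mir-30a-5p")
  expect_identical(normalize_mir_name("miR-30a-5p"), "mir-30a-5p")
  expect_identical(normalize_mir_name("hsa-let-7a-3p"), "let-7a-3p")
  expect_identical(normalize_mir_name("mmu-miR-155-5p"), "mir-155-5p")
  expect_identical(normalize_mir_name("miR-636"), "mir-636")
  expect_identical(normalize_mir_name(c("hsa-miR-1299", "MiR-23a-5p")),
                   c("mir-1299", "mir-23a-5p"))
})

test_that("summed context++ scores add over a gene's sites", {
  db <- target_db(data.frame(
    mir = c("miR-1-3p", "miR-1-3p"), gene_symbol = "G1",
    transcript_id = c("T1", "T1"), context_score = c(-0.2, -0.3)))
  s <- map_targets("miR-1-3p", "G1", db)
  expect_equal(s$per_gene$total_context_score, -0.5)
  expect_equal(s$per_gene$n_targeting_mirs, 1L)
})

test_that("map_targets equals the brute-force double loop on a toy db", {
  set.seed(30)
  mirs <- paste0("hsa-miR-", 1:5, "-5p")
  genes <- paste0("G", 1:10)
  rec <- do.call(rbind, lapply(mirs, function(m) {
    hit <- sample(genes, sample(2:6, 1))
    data.frame(mir = m, gene_symbol = hit,
               transcript_id = paste0(hit, "-201"),
               context_score = round(runif(length(hit), -0.6, -0.05), 3))
  }))
  db <- target_db(rec)
  universe <- paste0("G", 1:12)  # two genes absent from the db
  s <- map_targets(mirs, universe, db)
  # oracle: explicit double loop over (gene, mir) pairs
  for (g in s$per_gene$gene) {
    hits <- vapply(mirs, function(m)
      any(rec$mir == m & rec$gene_symbol == g), logical(1))
    expect_equal(s$per_gene$n_targeting_mirs[s$per_gene$gene == g],
                 sum(hits))
    expect_equal(s$per_gene$total_context_score[s$per_gene$gene == g],
                 sum(rec$context_score[rec$gene_symbol == g]))
  }
  for (m in mirs) {
    mn <- normalize_mir_name(m)
    expect_equal(s$per_mir$n_targets[s$per_mir$mir == mn],
                 length(unique(rec$gene_symbol[rec$mir == m])))
  }
  expect_equal(s$n_in_db, length(intersect(universe, rec$gene_symbol)))
  expect_equal(s$n_targeted, nrow(s$per_gene))
  # total scores are nonpositive when every site score is
  expect_true(all(s$per_gene$total_context_score <= 0))
})

test_that("an empty miR query yields an all-zero summary", {
  db <- target_db(data.frame(mir = "miR-1-3p", gene_symbol = "G1",
                             transcript_id = "T1", context_score = -0.2))
  s <- map_targets(character(0), c("G1", "G2"), db)
  expect_equal(s$n_targeted, 0)
  expect_equal(s$fraction_targeted, 0)
  expect_equal(nrow(s$per_gene), 0)
  expect_error(map_targets("miR-1-3p", character(0), db), "empty universe")
})

test_that("map_targets is monotone in the miR set", {
  res <- default_run()
  db <- res$dataset$target_db
  uni <- res$down_universe$genes
  mirs <- res$exclusive$mir_ids
  s_all <- map_targets(mirs, uni, db)
  s_sub <- map_targets(mirs[-1], uni, db)
  expect_gte(s_all$n_targeted, s_sub$n_targeted)
  both <- intersect(s_all$per_gene$gene, s_sub$per_gene$gene)
  expect_true(all(
    s_all$per_gene$n_targeting_mirs[match(both, s_all$per_gene$gene)] >=
      s_sub$per_gene$n_targeting_mirs[match(both, s_sub$per_gene$gene)]))
  # counting with multiplicity: per-miR totals cover every targeted gene
  expect_gte(sum(s_all$per_mir$n_targets), s_all$n_targeted)
})

test_that("multiplicity statistics follow their definitions", {
  s <- structure(list(
    per_gene = data.frame(gene = paste0("G", 1:4),
                          n_targeting_mirs = c(1L, 2L, 15L, 20L),
                          mir_list = "", total_context_score = -1),
    per_mir = data.frame(mir = c("a", "b"), n_targets = c(3L, 9L),
                         mean_context_score = -0.2),
    mirs_absent_from_db = character(0),
    n_universe_genes = 10, n_in_db = 8, n_targeted = 4,
    fraction_targeted = 0.5), class = "target_summary")
  m <- multiplicity_stats(s)
  expect_equal(m$frac_ge1, 4 / 8)
  expect_equal(m$frac_ge2, 3 / 4)
  expect_equal(m$frac_ge15, 2 / 4)
  expect_equal(m$targets_per_mir_mean, 6)
  expect_equal(m$targets_per_mir_min, 3)
  expect_equal(m$targets_per_mir_max, 9)
  # every targeted gene hit exactly once -> frac_ge2 is 0
  s$per_gene$n_targeting_mirs <- rep(1L, 4)
  expect_equal(multiplicity_stats(s)$frac_ge2, 0)
})

test_that("coverage contrast is antisymmetric and zero on identical input", {
  res <- default_run()
  down <- res$down_summary; up <- res$up_summary
  cc <- coverage_contrast(down, up)
  cc_rev <- coverage_contrast(up, down)
  expect_equal(cc$fraction_diff, -cc_rev$fraction_diff)
  expect_equal(cc$targets_per_mir_diff, -cc_rev$targets_per_mir_diff)
  same <- coverage_contrast(down, down)
  expect_equal(same$fraction_diff, 0)
  expect_equal(same$targets_per_mir_diff, 0)
  expect_false(same$down_exceeds_up)
})

test_that("miRs absent from the database are reported and excluded from averages", {
  res <- default_run()
  truth <- res$dataset$truth
  s <- res$down_summary
  expect_identical(s$mirs_absent_from_db, truth$mirs_absent_from_db)
  expect_equal(nrow(s$per_mir),
               length(truth$exclusive_mir_ids) -
                 length(truth$mirs_absent_from_db))
})
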