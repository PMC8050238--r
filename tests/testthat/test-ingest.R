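write_expr_fixture <- function(dir, genes, values, samples) {
  vp <- file.path(dir, "values.tsv"); mp <- file.path(dir, "meta.tsv")
  df <- data.frame(gene = genes, values, check.names = FALSE)
  names(df)[-1L] <- samples$sample_id
  utils::write.table(df, vp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(samples, mp, sep = "\t", quote = FALSE, row.names = FALSE)
  c(values = vp, meta = mp)
}

std_meta <- function(ids) data.frame(sample_id = ids, stage = 1L, structure = "AMY")

test_that("expression round-trips through writer and reader", {
  m <- matrix(c(1, 2, 3, 4, 5, 6, 7, 8, 0, 0.5, 2.5, 9), nrow = 3,
              byrow = TRUE, dimnames = list(c("GA", "GB", "GC"), NULL))
  x <- tiny_expression(m, stages = c(1L, 2L, 5L, 13L),
                       structures = c("AMY", "HIP", "STR", "MD"))
  d <- withr::local_tempdir()
  write_expression(x, file.path(d, "v.tsv"), file.path(d, "m.tsv"))
  y <- read_expression(file.path(d, "v.tsv"), file.path(d, "m.tsv"))
  expect_equal(dim(y$values), c(3L, 4L))
  expect_equal(y$values, x$values)
  expect_equal(y$samples, x$samples)
})

test_that("sample column missing from metadata is a hard error naming it", {
  d <- withr::local_tempdir()
  meta <- std_meta(c("s1", "s2"))
  fx <- write_expr_fixture(d, c("GA", "GB"), matrix(1:6, nrow = 2),
                           std_meta(c("s1", "s2", "s3")))
  utils::write.table(meta, fx[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(read_expression(fx[["values"]], fx[["meta"]]), "s3")
})

test_that("non-numeric cells are rejected with coordinates", {
  d <- withr::local_tempdir()
  writeLines(c("gene\ts1\ts2", "GA\t1.0\toops", "GB\t2\t3"),
             file.path(d, "v.tsv"))
  utils::write.table(std_meta(c("s1", "s2")), file.path(d, "m.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  err <- expect_error(read_expression(file.path(d, "v.tsv"),
                                      file.path(d, "m.tsv")))
  expect_match(conditionMessage(err), "GA")
  expect_match(conditionMessage(err), "s2")
})

test_that("duplicate gene rows collapse to the highest-mean row", {
  d <- withr::local_tempdir()
  fx <- write_expr_fixture(d, c("GA", "GA", "GB"),
                           rbind(c(1, 3), c(4, 6), c(7, 7)),
                           std_meta(c("s1", "s2")))
  x <- suppressMessages(read_expression(fx[["values"]], fx[["meta"]]))
  expect_equal(nrow(x$values), 2L)
  expect_equal(unname(x$values["GA", ]), c(4, 6))  # mean 5 beats mean 2
})

test_that("brain-expression filter removes on either criterion", {
  ## hand-computed: GA constant 10 -> CV 0; GB all zero -> both criteria;
  ## GC (1,2,4,8): pop sd 2.681, mean 3.75, CV 0.715 and log2(9) >= 0.4 -> kept;
  ## GD low everywhere: log2(0.1+1) = 0.138 < 0.4 in all samples.
  m <- rbind(GA = c(10, 10, 10, 10), GB = c(0, 0, 0, 0),
             GC = c(1, 2, 4, 8), GD = c(0.1, 0.05, 0.1, 0.02))
  x <- tiny_expression(m)
  out <- suppressMessages(filter_brain_expressed(x))
  expect_equal(rownames(out$expression$values), "GC")
  expect_setequal(out$removed$gene, c("GA", "GB", "GD"))
  expect_equal(out$removed$reason[out$removed$gene == "GA"], "low CV")
  expect_equal(out$removed$reason[out$removed$gene == "GB"],
               "low intensity; low CV")
  ## AND logic keeps genes failing only one criterion
  out_and <- suppressMessages(filter_brain_expressed(
    x, expression_filter_params(logic = "and")))
  expect_setequal(rownames(out_and$expression$values), c("GA", "GC", "GD"))
})

test_that("filter is invariant to sample order", {
  withr::local_seed(11)
  m <- matrix(rexp(60, rate = 2), nrow = 6,
              dimnames = list(sprintf("G%d", 1:6), NULL))
  x <- tiny_expression(m)
  perm <- sample(ncol(m))
  xp <- tiny_expression(m[, perm, drop = FALSE])
  a <- suppressMessages(filter_brain_expressed(x))
  b <- suppressMessages(filter_brain_expressed(xp))
  expect_setequal(rownames(a$expression$values), rownames(b$expression$values))
})

test_that("interaction reader is header-driven and filters physical rows", {
  d <- withr::local_tempdir()
  rows <- data.frame(
    type = c("physical", "genetic", "physical", "genetic", "physical"),
    b = c("B", "C", "D", "E", "F"), a = c("A", "A", "a", "B", "B"))
  names(rows) <- c("Experimental System Type", "Official Symbol Interactor B",
                   "Official Symbol Interactor A")
  utils::write.table(rows, file.path(d, "ppi.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  tab <- suppressMessages(read_interactions(file.path(d, "ppi.tsv")))
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$gene_a, c("A", "A", "B"))  # case-normalized
  all5 <- suppressMessages(read_interactions(file.path(d, "ppi.tsv"),
                                             physical_only = FALSE))
  expect_equal(nrow(all5), 5L)
  ## minimal dialect
  utils::write.table(
    data.frame(gene_a = "X", gene_b = "Y", system_type = "physical"),
    file.path(d, "mini.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(nrow(suppressMessages(read_interactions(file.path(d, "mini.tsv")))), 1L)
  ## wrong headers -> error listing the expected names
  utils::write.table(data.frame(x = 1, y = 2), file.path(d, "bad.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_interactions(file.path(d, "bad.tsv")),
               "Official Symbol Interactor A")
  ## empty data section
  writeLines("gene_a\tgene_b\tsystem_type", file.path(d, "empty.tsv"))
  expect_equal(nrow(suppressMessages(read_interactions(file.path(d, "empty.tsv")))), 0L)
})

test_that("interactome cleaning removes self-loops, duplicates and non-brain pairs", {
  tab <- data.frame(gene_a = c("A", "B", "A", "A"),
                    gene_b = c("B", "A", "A", "C"),
                    system_type = "physical")
  hi <- suppressMessages(build_brain_interactome(tab, c("A", "B")))
  expect_equal(nrow(hi$edges), 1L)
  expect_equal(hi$edges$a, "A")
  expect_equal(hi$edges$b, "B")
  expect_setequal(hi$nodes, c("A", "B"))
  empty <- suppressMessages(build_brain_interactome(tab, c("X", "Y")))
  expect_equal(nrow(empty$edges), 0L)
})

test_that("interactome matches a set-based oracle on random input", {
  withr::local_seed(21)
  genes <- sprintf("G%02d", 1:20)
  tab <- data.frame(gene_a = sample(genes, 100, replace = TRUE),
                    gene_b = sample(genes, 100, replace = TRUE),
                    system_type = "physical")
  hi <- suppressMessages(build_brain_interactome(tab, genes))
  oracle <- unique(apply(cbind(tab$gene_a, tab$gene_b), 1L, function(r)
    if (r[1] == r[2]) NA_character_ else paste(sort(r), collapse = "|")))
  oracle <- oracle[!is.na(oracle)]
  expect_equal(nrow(hi$edges), length(oracle))
  expect_setequal(paste(hi$edges$a, hi$edges$b, sep = "|"), oracle)
})

test_that("locus query list yields 21 genes after the two stated exclusions", {
  path <- system.file("extdata", "7q11_23_genes.txt", package = "stnet")
  listed <- read_gene_list(path)
  expect_length(unique(listed), 23L)
  q <- suppressMessages(load_query_genes(
    path,
    exclusions = c(FKBP6 = "not expressed in brain",
                   WBSCR28 = "not expressed in brain"),
    brain_genes = setdiff(listed, c("FKBP6", "WBSCR28"))))
  expect_length(q$genes, 21L)
  expect_setequal(q$excluded$gene, c("FKBP6", "WBSCR28"))
})

test_that("query list uses set semantics and warns on stray exclusions", {
  d <- withr::local_tempdir()
  writeLines(c("A", "B", "A", "# comment", "C"), file.path(d, "q.txt"))
  q <- suppressMessages(load_query_genes(file.path(d, "q.txt"),
                                         brain_genes = c("A", "B", "C")))
  expect_equal(sort(q$genes), c("A", "B", "C"))
  expect_warning(
    suppressMessages(load_query_genes(file.path(d, "q.txt"),
                                      exclusions = c(ZZZ = "stray"),
                                      brain_genes = c("A", "B", "C"))),
    "ZZZ")
  expect_error(
    suppressMessages(load_query_genes(file.path(d, "q.txt"),
                                      brain_genes = "NONE")),
    "empty")
})
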