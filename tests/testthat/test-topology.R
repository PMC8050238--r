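subnet <- function(key, query_nodes, partner_nodes, edges) {
  edges$rho <- edges$rho %||% 0.9
  edges$kind <- "query-partner"
  structure(list(key = key, query_nodes = query_nodes,
                 partner_nodes = partner_nodes, edges = edges),
            class = "stn_subnetwork")
}

test_that("overlap counts behave at the identical and disjoint extremes", {
  e <- data.frame(a = "Q1", b = "X1")
  same <- lapply(c("P1R1", "P1R3", "P4R3"), subnet,
                 query_nodes = c("Q1", "Q2"), partner_nodes = c("X1", "X2"),
                 edges = e)
  ov <- network_overlap(same, catalog_query = 23L)
  expect_equal(ov$query$frac_shared_union, 1)
  expect_equal(ov$partner$frac_shared_union, 1)
  expect_equal(ov$query$shared_all, 2L)
  expect_equal(ov$query$frac_shared_catalog, 2 / 23)

  disj <- lapply(1:3, function(i)
    subnet(paste0("N", i), "Q1", sprintf("X%d", i), e))
  ov2 <- network_overlap(disj)
  expect_equal(ov2$partner$shared_all, 0L)
  expect_equal(unname(ov2$partner$exactly_k), c(3L, 0L, 0L))
})

test_that("overlap counts equal brute-force membership tabulation", {
  withr::local_seed(61)
  for (i in 1:10) {
    sets_q <- lapply(1:3, function(j) sample(sprintf("Q%02d", 1:20), sample(3:12, 1)))
    sets_p <- lapply(1:3, function(j) sample(sprintf("X%02d", 1:40), sample(5:25, 1)))
    nets <- lapply(1:3, function(j)
      subnet(paste0("N", j), sets_q[[j]], sets_p[[j]], data.frame(a = "Q01", b = "X01")))
    ov <- network_overlap(nets)
    for (cat in c("query", "partner")) {
      sets <- if (cat == "query") sets_q else sets_p
      u <- unique(unlist(sets))
      counts <- sapply(u, function(g) sum(vapply(sets, function(s) g %in% s, logical(1))))
      for (k in 1:3)
        expect_equal(unname(ov[[cat]]$exactly_k[paste0("k", k)]), sum(counts == k))
      expect_equal(ov[[cat]]$union_size, length(u))
      expect_equal(sum(ov[[cat]]$exactly_k), length(u))
    }
  }
})

ratio_fixture <- function(pa, pb) {
  ## two one-query-gene networks with prescribed partner sets
  ea <- data.frame(a = rep("Q1", length(pa)), b = pa)
  eb <- data.frame(a = rep("Q1", length(pb)), b = pb)
  list(a = subnet("A", "Q1", pa, ea), b = subnet("B", "Q1", pb, eb))
}

test_that("partner ratios match hand-computed cases", {
  f <- ratio_fixture(c("X", "Y"), c("X", "Y"))
  pr <- partner_ratios(f$a, f$b, "Q1")
  expect_equal(c(pr$r_unique_a, pr$r_unique_b, pr$r_shared), c(0, 0, 1))

  f2 <- ratio_fixture("X", "Y")
  pr2 <- partner_ratios(f2$a, f2$b, "Q1")
  expect_equal(c(pr2$r_unique_a, pr2$r_unique_b, pr2$r_shared), c(0.5, 0.5, 0))

  f3 <- ratio_fixture(c("X", "Y", "Z"), c("Y", "Z", "W"))
  pr3 <- partner_ratios(f3$a, f3$b, "Q1")
  expect_equal(c(pr3$r_unique_a, pr3$r_unique_b, pr3$r_shared),
               c(0.25, 0.25, 0.5))
})

test_that("partner ratios sum to one over random partner sets", {
  withr::local_seed(62)
  for (i in 1:20) {
    pool <- sprintf("X%02d", 1:30)
    f <- ratio_fixture(sample(pool, sample(1:20, 1)),
                       sample(pool, sample(1:20, 1)))
    pr <- partner_ratios(f$a, f$b, "Q1")
    expect_equal(pr$r_unique_a + pr$r_unique_b + pr$r_shared, 1,
                 tolerance = 1e-12)
  }
  ## genes with no partners anywhere are skipped
  f <- ratio_fixture("X", "Y")
  pr <- suppressMessages(partner_ratios(f$a, f$b, c("Q1", "Q9")))
  expect_equal(pr$gene, "Q1")
})

test_that("one-way ANOVA recovers classical behaviour", {
  ## equal group means -> F = 0, p = 1
  a0 <- one_way_anova(list(c(1, 2, 3), c(2, 1, 3)))
  expect_equal(a0$F, 0, tolerance = 1e-12)
  expect_equal(a0$p, 1)
  ## two groups: F equals the squared pooled-t statistic
  withr::local_seed(63)
  for (i in 1:20) {
    g1 <- rnorm(sample(3:9, 1)); g2 <- rnorm(sample(3:9, 1), mean = 0.5)
    a <- one_way_anova(list(g1, g2))
    tt <- t.test(g1, g2, var.equal = TRUE)
    expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(a$p, tt$p.value, tolerance = 1e-10)
    expect_equal(a$df_between, 1)
    expect_equal(a$df_within, length(g1) + length(g2) - 2)
  }
  expect_error(one_way_anova(list(1:3)), "2 groups")
  expect_error(one_way_anova(list(1:3, 5)), "at least 2 values")
})

test_that("ANOVA F is invariant to shifting and scaling all observations", {
  withr::local_seed(64)
  groups <- list(rnorm(5), rnorm(6, 1), rnorm(4, -1))
  f0 <- one_way_anova(groups)$F
  expect_equal(one_way_anova(lapply(groups, `+`, 10))$F, f0, tolerance = 1e-9)
  expect_equal(one_way_anova(lapply(groups, `*`, 3.7))$F, f0, tolerance = 1e-9)
})

test_that("null ANOVA p-values are approximately uniform", {
  withr::local_seed(65)
  p <- replicate(300, one_way_anova(list(rnorm(5), rnorm(5), rnorm(5)))$p)
  expect_gt(stats::ks.test(p, "punif")$p.value, 0.001)
})

as_net <- function(edges, nodes = sort(unique(c(edges$a, edges$b)))) {
  edges$rho <- 0.9
  structure(list(key = "K", edges = edges, nodes = nodes),
            class = "stn_network")
}

test_that("radiality matches closed forms on K4 and a path", {
  k4 <- as_net(data.frame(a = c("A", "A", "A", "B", "B", "C"),
                          b = c("B", "C", "D", "C", "D", "D")))
  r <- radiality(k4)
  expect_equal(r$radiality, rep(1, 4))
  path <- as_net(data.frame(a = c("A", "B"), b = c("B", "C")))
  rp <- radiality(path)
  expect_equal(rp$radiality[rp$gene == "B"], 1)
  expect_equal(rp$radiality[rp$gene %in% c("A", "C")], c(0.75, 0.75))
})

test_that("radiality agrees with the BFS oracle on random graphs", {
  withr::local_seed(66)
  for (i in 1:30) {
    n <- sample(5:40, 1L)
    edges <- random_edges(n, sample(n:(3 * n), 1L))
    net <- as_net(edges)
    got <- radiality(net)
    want <- oracle_radiality(edges, net$nodes)
    expect_equal(stats::setNames(got$radiality, got$gene), want[got$gene],
                 tolerance = 1e-12)
    expect_true(all(got$radiality >= 0 & got$radiality <= 1))
  }
})

test_that("driver identification uses radiality, then degree, then symbol", {
  star <- as_net(data.frame(a = rep("HUB", 4), b = c("A", "B", "C", "D")))
  r <- radiality(star)
  expect_equal(identify_driver(r, c("HUB", "A"))$gene, "HUB")
  ## two components with equal radiality 1 but different degree
  two <- as_net(data.frame(a = c("A", "A", "A", "X"), b = c("B", "C", "D", "Y")))
  rt <- radiality(two)
  expect_equal(rt$radiality[rt$gene %in% c("A", "X")], c(1, 1))
  d <- suppressMessages(identify_driver(rt, c("A", "X")))
  expect_equal(d$gene, "A")  # degree 3 beats degree 1
  ## pure tie falls back to the lexicographically first symbol
  tie <- as_net(data.frame(a = c("M", "K"), b = c("N", "L")))
  expect_equal(suppressMessages(identify_driver(radiality(tie), c("M", "K")))$gene,
               "K")
  expect_error(identify_driver(r, "ZZZ"), "no candidate")
})

test_that("driver matches an argmax oracle on random graphs", {
  withr::local_seed(67)
  for (i in 1:10) {
    edges <- random_edges(25, 50)
    net <- as_net(edges)
    r <- radiality(net)
    cand <- sample(net$nodes, 8L)
    d <- suppressMessages(identify_driver(r, cand))
    sub <- r[r$gene %in% cand, ]
    expect_equal(d$radiality, max(sub$radiality))
    best <- sub[sub$radiality == max(sub$radiality), ]
    best <- best[order(-best$degree, best$gene), ]
    expect_equal(d$gene, best$gene[1L])
  }
})

test_that("network comparison ANOVA wires ratios into groups", {
  withr::local_seed(68)
  pool <- sprintf("X%02d", 1:30)
  qs <- sprintf("Q%d", 1:8)
  mk <- function(key) {
    e <- do.call(rbind, lapply(qs, function(q)
      data.frame(a = q, b = sample(pool, sample(2:8, 1)))))
    subnet(key, qs, sort(unique(e$b)), e)
  }
  cmp <- suppressMessages(compare_networks_anova(mk("P1R3"), mk("P4R3"), qs))
  expect_s3_class(cmp$anova, "stn_anova")
  expect_equal(cmp$anova$df_between, 2)
  expect_equal(cmp$comparison, "P1R3 vs P4R3")
  pr <- cmp$ratios
  direct <- one_way_anova(list(pr$r_unique_a, pr$r_unique_b, pr$r_shared))
  expect_equal(cmp$anova$F, direct$F, tolerance = 1e-12)
  cmp2 <- suppressMessages(compare_networks_anova(mk("A"), mk("B"), qs,
                                                  grouping = "two_group"))
  expect_equal(cmp2$anova$df_between, 1)
})
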