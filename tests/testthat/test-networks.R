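# longitudinal abundance generator with l latent-factor blocks: taxa in
# the same block share a within-subject latent signal, everything else is
# independent noise
make_block_data <- function(ns = 15, nt = 4, blocks = list(1:4, 5:8, 9:12),
                            n_noise = 10, coupling = 1.2, seed = 1) {
  set.seed(seed)
  n <- ns * nt
  subj <- rep(paste0("s", seq_len(ns)), each = nt)
  p <- max(unlist(blocks)) + n_noise
  m <- matrix(rnorm(n * p, sd = 0.5), n, p)
  for (b in blocks) {
    latent <- rnorm(n)
    m[, b] <- m[, b] + coupling * latent
  }
  colnames(m) <- paste0("t", seq_len(p))
  list(mat = m, subject = subj, blocks = blocks)
}

test_that("planted co-varying blocks are recovered as edges, noise is not", {
  false_edges <- integer(5); found <- logical(5)
  for (i in 1:5) {
    bd <- make_block_data(seed = i)
    net <- build_network(bd$mat, bd$subject)
    key <- paste(pmin(net$edges$taxon_a, net$edges$taxon_b),
                 pmax(net$edges$taxon_a, net$edges$taxon_b))
    planted <- unlist(lapply(bd$blocks, function(b) {
      pr <- combn(paste0("t", b), 2)
      paste(pmin(pr[1, ], pr[2, ]), pmax(pr[1, ], pr[2, ]))
    }))
    found[i] <- mean(planted %in% key) > 0.8
    false_edges[i] <- sum(!key %in% planted)
  }
  expect_gte(sum(found), 4)
  expect_lte(mean(false_edges), 1)
})

test_that("independent taxa yield essentially no significant edges", {
  totals <- vapply(1:5, function(i) {
    set.seed(100 + i)
    m <- matrix(rnorm(60 * 21), 60, 21,
                dimnames = list(NULL, paste0("t", 1:21)))
    nrow(build_network(m, rep(paste0("s", 1:15), each = 4))$edges)
  }, numeric(1))
  expect_lte(mean(totals), 1)
})

test_that("edge filter limits and taxon-count guard behave", {
  bd <- make_block_data(seed = 3)
  net <- build_network(bd$mat, bd$subject, r_min = 1.0)
  expect_equal(nrow(net$edges), 0)
  expect_error(build_network(bd$mat[, 1:2], bd$subject), "3 taxa")
  # edges satisfy the dual filter by construction
  net2 <- build_network(bd$mat, bd$subject, r_min = 0.5, q_max = 0.05)
  expect_true(all(abs(net2$edges$r) > 0.5 & net2$edges$q < 0.05))
})

test_that("module detection separates disconnected cliques exactly", {
  bd <- make_block_data(blocks = list(1:4, 5:8), n_noise = 2,
                        coupling = 3, seed = 9)
  net <- build_network(bd$mat, bd$subject)
  net <- detect_modules(net, seed = 1)
  mod <- setNames(net$nodes$module, net$nodes$taxon)
  m1 <- unique(mod[paste0("t", 1:4)])
  m2 <- unique(mod[paste0("t", 5:8)])
  expect_length(m1, 1)
  expect_length(m2, 1)
  expect_false(m1 == m2)
})

test_that("planted 3-block partitions are recovered with high agreement", {
  agree <- vapply(1:5, function(i) {
    bd <- make_block_data(coupling = 2, n_noise = 4, seed = 40 + i)
    net <- build_network(bd$mat, bd$subject)
    net <- detect_modules(net, seed = 1)
    truth <- rep(seq_along(bd$blocks), lengths(bd$blocks))
    names(truth) <- paste0("t", unlist(bd$blocks))
    common <- intersect(names(truth), net$nodes$taxon)
    mclust::adjustedRandIndex(
      truth[common],
      net$nodes$module[match(common, net$nodes$taxon)])
  }, numeric(1))
  expect_gte(mean(agree), 0.9)
})

test_that("Zi-Pi follow their closed forms on a hand-built graph", {
  # two triangles bridged by one node ("br") with one edge into each
  edges <- data.frame(
    taxon_a = c("a1", "a1", "a2", "b1", "b1", "b2", "br", "br"),
    taxon_b = c("a2", "a3", "a3", "b2", "b3", "b3", "a1", "b1"),
    r = 0.9, q = 0.001, sign = "positive", stringsAsFactors = FALSE)
  nodes <- data.frame(taxon = c("a1", "a2", "a3", "b1", "b2", "b3", "br"),
                      stringsAsFactors = FALSE)
  net <- structure(list(edges = edges, nodes = nodes, n_taxa = 7,
                        taxa = nodes$taxon, df = 10),
                   class = "co_network")
  net$nodes$module <- c(1, 1, 1, 2, 2, 2, 3)
  net <- zi_pi(net)
  got <- setNames(net$nodes$Pi, net$nodes$taxon)
  # bridge node: degree 2 split over modules 1 and 2 -> Pi = 1 - 2*(1/2)^2
  expect_equal(unname(got["br"]), 0.5)
  # a2: both edges inside its own module -> Pi = 0
  expect_equal(unname(got["a2"]), 0)
  # a1: 2 within + 1 to the bridge module: Pi = 1 - (2/3)^2 - (1/3)^2
  expect_equal(unname(got["a1"]), 1 - 4 / 9 - 1 / 9)
  # singleton module -> Zi = 0 by the SD = 0 convention
  expect_equal(net$nodes$Zi[net$nodes$taxon == "br"], 0)
  # role partition covers all nodes
  expect_true(all(net$nodes$role %in%
                    c("peripheral", "connector", "module hub",
                      "network hub")))
  # sum of per-module degrees equals total degree (brute force)
  for (v in nodes$taxon) {
    k <- sum(edges$taxon_a == v | edges$taxon_b == v)
    expect_equal(net$nodes$degree[net$nodes$taxon == v], k)
  }
  # node with degree 4 split evenly across 2 modules -> Pi = 0.5
  # (checked via the bridge above at degree 2; same formula)
})

test_that("Pi respects its upper bound and evenly-connected modules give Zi 0", {
  bd <- make_block_data(coupling = 2, seed = 60)
  net <- zi_pi(detect_modules(build_network(bd$mat, bd$subject), seed = 1))
  expect_true(all(net$nodes$Pi >= -1e-12 & net$nodes$Pi <= 1))
  for (i in seq_len(nrow(net$nodes))) {
    v <- net$nodes$taxon[i]
    touched <- unique(c(
      net$nodes$module[match(net$edges$taxon_b[net$edges$taxon_a == v],
                             net$nodes$taxon)],
      net$nodes$module[match(net$edges$taxon_a[net$edges$taxon_b == v],
                             net$nodes$taxon)]))
    expect_lte(net$nodes$Pi[i], 1 - 1 / length(touched) + 1e-12)
  }
})

test_that("network comparison counts shared and unique edges", {
  bd <- make_block_data(seed = 2)
  net <- build_network(bd$mat, bd$subject)
  same <- compare_networks(net, net)
  expect_equal(same$a_only, 0)
  expect_equal(same$b_only, 0)
  expect_equal(same$shared, nrow(net$edges))
  # disjoint edge sets of sizes 3 and 5
  mk <- function(pairs) {
    e <- data.frame(taxon_a = pairs[, 1], taxon_b = pairs[, 2], r = 0.8,
                    q = 0.01, sign = "positive",
                    stringsAsFactors = FALSE)
    structure(list(edges = e, nodes = data.frame(
      taxon = unique(c(pairs))), n_taxa = 12,
      taxa = paste0("t", 1:12), df = 5), class = "co_network")
  }
  a <- mk(cbind(paste0("t", 1:3), paste0("t", 4:6)))
  b <- mk(cbind(paste0("t", 7:11), paste0("t", c(8:11, 12))))
  cmp <- compare_networks(a, b)
  expect_equal(cmp$shared, 0)
  expect_equal(cmp$a_only, 3)
  expect_equal(cmp$b_only, 5)
})

test_that("groups with extra coupling form more edges than their counterpart", {
  wins <- vapply(1:5, function(i) {
    strong <- make_block_data(coupling = 1.5, seed = 200 + i)
    weak <- make_block_data(coupling = 0.4, seed = 300 + i)
    na <- build_network(strong$mat, strong$subject)
    nb <- build_network(weak$mat, weak$subject)
    cmp <- compare_networks(na, nb)
    cmp$a_only > cmp$b_only
  }, logical(1))
  expect_gte(sum(wins), 5 * 0.9)
})
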