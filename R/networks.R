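#' Build a longitudinal co-abundance network
#'
#' Computes the repeated-measures correlation (see [rmcorr_matrix()]) for
#' every taxon pair of an abundance matrix, BH-adjusts the p-values
#' across all pairs, and keeps edges with `|r| > r_min` and `q < q_max`
#' (defaults 0.5 / 0.05). Isolated taxa are dropped from the graph but
#' counted in the report.
#'
#' @param abundance samples x taxa matrix (CLR values by default
#'   convention; rarefied counts also accepted).
#' @param subject subject ID per row.
#' @param r_min minimal absolute correlation for an edge.
#' @param q_max maximal BH q-value for an edge.
#' @return object of class `co_network`: `edges` (data.frame taxon_a,
#'   taxon_b, r, q, sign), `nodes` (taxa with >= 1 edge), `n_taxa`
#'   (taxa tested), `df`; module/role columns are filled by
#'   [detect_modules()] and [zi_pi()].
#' @export
build_network <- function(abundance, subject, r_min = 0.5, q_max = 0.05) {
  abundance <- as.matrix(abundance)
  m <- ncol(abundance)
  if (m < 3) stop("need at least 3 taxa")
  rm <- rmcorr_matrix(abundance, subject)
  ut <- upper.tri(rm$r)
  idx <- which(ut, arr.ind = TRUE)
  pairs <- data.frame(taxon_a = colnames(abundance)[idx[, 1]],
                      taxon_b = colnames(abundance)[idx[, 2]],
                      r = rm$r[ut], p = rm$p[ut],
                      stringsAsFactors = FALSE)
  pairs$q <- bh_adjust(pairs$p)
  keep <- abs(pairs$r) > r_min & pairs$q < q_max
  edges <- pairs[keep, c("taxon_a", "taxon_b", "r", "q")]
  edges$sign <- ifelse(edges$r > 0, "positive", "negative")
  rownames(edges) <- NULL
  nodes <- data.frame(taxon = sort(unique(c(edges$taxon_a,
                                            edges$taxon_b))),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, nodes = nodes, n_taxa = m,
                 taxa = colnames(abundance), df = rm$df,
                 r_min = r_min, q_max = q_max),
            class = "co_network")
}

#' @export
print.co_network <- function(x, ...) {
  cat("co_network:", nrow(x$edges), "edges over", nrow(x$nodes),
      "connected taxa (", x$n_taxa, "tested )\n")
  if (!is.null(x$nodes$module))
    cat("  modules:", length(unique(x$nodes$module)), "\n")
  invisible(x)
}

as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("taxon_a", "taxon_b")], directed = FALSE,
    vertices = net$nodes$taxon)
  igraph::E(g)$weight <- abs(net$edges$r)
  igraph::E(g)$r <- net$edges$r
  g
}

#' Detect co-abundance modules
#'
#' Modularity-maximising partition (Louvain) of the network on absolute
#' correlation weights; edge signs are kept as attributes only, so
#' modules group taxa with tightly coordinated abundance changes of
#' either direction. Disconnected components can never share a module.
#'
#' @param net a [build_network()] result.
#' @param seed integer seed (community detection ties).
#' @return `net` with a `module` column added to `nodes`.
#' @export
detect_modules <- function(net, seed = 1L) {
  stopifnot(inherits(net, "co_network"))
  if (nrow(net$edges) < 1) stop("network has no edges")
  g <- as_igraph(net)
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, weights = igraph::E(g)$weight)
  net$nodes$module <- igraph::membership(comm)[net$nodes$taxon]
  net$modularity <- igraph::modularity(comm)
  net
}

#' Within- and among-module connectivity (Zi-Pi) node roles
#'
#' For each connected node, `Zi` is the z-score of its within-module
#' degree relative to its module (0 when the module's within-degrees have
#' zero SD), and `Pi = 1 - sum_s (k_is / k_i)^2` is the participation of
#' its edges across modules. Roles follow the conventional cutoffs:
#' module hub `Zi >= 2.5 & Pi <= pi_thresh`, connector `Zi < 2.5 &
#' Pi > pi_thresh`, network hub when both are exceeded, peripheral
#' otherwise.
#'
#' @param net a network with modules assigned ([detect_modules()]).
#' @param zi_thresh,pi_thresh role cutoffs (defaults 2.5 and 0.62).
#' @return `net` with `Zi`, `Pi`, `role` columns added to `nodes`.
#' @export
zi_pi <- function(net, zi_thresh = 2.5, pi_thresh = 0.62) {
  stopifnot(inherits(net, "co_network"))
  if (is.null(net$nodes$module)) stop("run detect_modules() first")
  nodes <- net$nodes$taxon
  mod <- stats::setNames(net$nodes$module, nodes)
  ea <- net$edges$taxon_a; eb <- net$edges$taxon_b
  deg_to_module <- function(v, s) # edges from node v into module s
    sum((ea == v & mod[eb] == s) | (eb == v & mod[ea] == s))
  k <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) k[v] <- sum(ea == v | eb == v)
  k_within <- vapply(nodes, function(v) deg_to_module(v, mod[v]),
                     numeric(1))
  zi <- numeric(length(nodes))
  for (s in unique(mod)) {
    members <- nodes[mod == s]
    kw <- k_within[members]
    sdv <- stats::sd(kw)
    zi[match(members, nodes)] <-
      if (is.na(sdv) || sdv == 0) 0 else (kw - mean(kw)) / sdv
  }
  pi_v <- vapply(nodes, function(v) {
    ks <- vapply(unique(mod), function(s) deg_to_module(v, s), numeric(1))
    1 - sum((ks / k[v])^2)
  }, numeric(1))
  role <- ifelse(zi >= zi_thresh & pi_v > pi_thresh, "network hub",
          ifelse(zi >= zi_thresh, "module hub",
          ifelse(pi_v > pi_thresh, "connector", "peripheral")))
  net$nodes$degree <- unname(k)
  net$nodes$Zi <- zi
  net$nodes$Pi <- unname(pi_v)
  net$nodes$role <- role
  net
}

#' Compare two co-abundance networks
#'
#' Intersects the edge sets of two networks over the same taxon universe
#' (edges matched on unordered taxon pairs) and summarises each network.
#'
#' @param net_a,net_b [build_network()] results over the same taxa.
#' @return list: `shared`, `a_only`, `b_only` edge counts; per-network
#'   `summary` (edges, density over tested pairs, mean |r|).
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "co_network"), inherits(net_b, "co_network"))
  if (!is.null(net_a$taxa) && !is.null(net_b$taxa) &&
      !length(intersect(net_a$taxa, net_b$taxa)))
    stop("networks have disjoint taxon universes")
  key <- function(net) {
    a <- pmin(net$edges$taxon_a, net$edges$taxon_b)
    b <- pmax(net$edges$taxon_a, net$edges$taxon_b)
    paste(a, b, sep = "|")
  }
  ka <- key(net_a); kb <- key(net_b)
  summ <- function(net) {
    n_pairs <- choose(net$n_taxa, 2)
    data.frame(edges = nrow(net$edges),
               density = nrow(net$edges) / n_pairs,
               mean_abs_r = if (nrow(net$edges)) mean(abs(net$edges$r))
                            else NA_real_)
  }
  list(shared = sum(ka %in% kb),
       a_only = sum(!ka %in% kb),
       b_only = sum(!kb %in% ka),
       summary = rbind(a = summ(net_a), b = summ(net_b)))
}

#' Write a network to TSV edge and node tables
#'
#' @param net a [co_network].
#' @param edges_path,nodes_path output TSVs.
#' @export
write_network <- function(net, edges_path, nodes_path) {
  utils::write.table(net$edges, edges_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(net$nodes, nodes_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(net)
}
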