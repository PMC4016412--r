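# Shared fixture builders. Everything is generated in code; nothing is
# read from disk except files the tests write themselves.

# node graph assembled directly (bypasses collapse_multinodes) for tests
# that need full control over topology
make_graph <- function(adjacency, node_genes = NULL, id = "test") {
  n <- nrow(adjacency)
  if (is.null(node_genes)) node_genes <- as.list(sprintf("g%03d", seq_len(n)))
  names(node_genes) <- sprintf("N%03d", seq_len(n))
  dimnames(adjacency) <- list(names(node_genes), names(node_genes))
  structure(list(nodes = node_genes,
                 node_of_gene = stats::setNames(
                   rep(names(node_genes), lengths(node_genes)),
                   unlist(node_genes)),
                 adjacency = adjacency != 0,
                 representation_id = id),
            class = "dawn_nodegraph")
}

make_node_scores <- function(g, p) {
  data.frame(node = names(g$nodes), n_genes = lengths(g$nodes),
             p_min = p, z = p_to_z(p), scored = !is.na(p),
             stringsAsFactors = FALSE)
}

# ring lattice: every node connected to its k nearest neighbours
ring_adj <- function(n, k = 4) {
  a <- matrix(FALSE, n, n)
  for (d in seq_len(k / 2)) {
    i <- seq_len(n)
    j <- ((i - 1 + d) %% n) + 1
    a[cbind(i, j)] <- TRUE
    a[cbind(j, i)] <- TRUE
  }
  a
}

rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  s <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  (choose(n, 2) + 2 * s - sa - sb) / choose(n, 2)
}

# one shared default-scenario run, computed lazily and reused across
# test files in this session
.cache <- new.env(parent = emptyenv())
cached_run <- function() {
  if (is.null(.cache$run)) {
    sc <- synth_scenario(seed = 42)
    cfg <- dawn_config(seed = 42)
    prepared <- dawn_prepare(sc$expression, cfg)
    res <- dawn_score(prepared, sc$scores, cfg)
    res$prepared <- prepared
    .cache$run <- list(scenario = sc, config = cfg, result = res)
  }
  .cache$run
}
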