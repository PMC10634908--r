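# Independent brute-force oracles used to cross-check the implementation.
# These deliberately avoid the code paths (and the graph library calls)
# they are checking.

# Circular distance by explicit wrap search over k in {-1, 0, 1}.
oracle_phase_difference <- function(phi1, phi2, period = 24) {
  d1 <- (phi1 %% period) - (phi2 %% period)
  vapply(d1, function(d) min(abs(d + period * c(-1, 0, 1))), 0)
}

# All-pairs hop distances by breadth-first search over an edge data.frame,
# written directly against adjacency lists.
oracle_all_pairs_bfs <- function(edges, nodes) {
  adj <- setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  D <- matrix(Inf, length(nodes), length(nodes),
              dimnames = list(nodes, nodes))
  for (s in nodes) {
    dist <- setNames(rep(Inf, length(nodes)), nodes)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      u <- queue[1]; queue <- queue[-1]
      for (v in adj[[u]]) {
        if (is.infinite(dist[v])) {
          dist[v] <- dist[u] + 1
          queue <- c(queue, v)
        }
      }
    }
    D[s, ] <- dist
  }
  D
}

# Small deterministic two-experiment, two-condition study built from a
# planted truth; returns matrices, truth tables and the network.
make_small_study <- function(n_nodes = 200, frac_cycling = 0.3,
                             coupling = 0, n_smooth = 0, noise_cv = 0.1,
                             jitter_sd = 0.25, seed = 1) {
  net <- generate_network(n_nodes, 8, "erdos_renyi", seed = seed)
  mats <- list(); truths <- list()
  for (cond in c("18C", "25C")) {
    truth <- plant_phases(net, frac_cycling, coupling = coupling,
                          n_smooth = n_smooth,
                          seed = substream_seed(seed, cond),
                          condition = cond)
    truths[[cond]] <- truth
    design <- sim_design(noise_cv = noise_cv, phase_jitter_sd = jitter_sd,
                         seed = substream_seed(seed, paste0("d", cond)))
    mats <- c(mats, simulate_experiment(truth, design))
  }
  list(net = net, truths = truths, matrices = mats)
}
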