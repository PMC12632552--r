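# Shared fixtures and oracles, all generated in code at test time.

# small deterministic peptides reused across files
test_peptide <- function(sequence = "ACDEFGHIKLMN", preset = "helix",
                         seed = 3L) {
  build_ideal_peptide(sequence, preset, seed = seed)
}

# independent brute-force edge oracle: all ordered pairs within cutoff
brute_force_edges <- function(xyz, cutoff) {
  n <- nrow(xyz)
  out <- NULL
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) <= cutoff) {
      out <- rbind(out, c(dst = i, src = j))
    }
  }
  out[order(out[, "dst"], out[, "src"]), , drop = FALSE]
}

# random point cloud as a graph-ready atom table
random_cloud <- function(n, seed, spread = 8) {
  set.seed(seed)
  data.frame(x = runif(n, 0, spread), y = runif(n, 0, spread),
             z = runif(n, 0, spread),
             element = sample(c("C", "N", "O", "S"), n, replace = TRUE),
             residue = rep(seq_len(max(1, n %/% 4)), length.out = n))
}

# finite-difference gradient comparison for a tape-graph builder
expect_grad_matches <- function(build, xs, tol = 1e-5) {
  td_reset()
  nodes <- lapply(xs, td_param)
  root <- build(nodes)
  td_backward(root)
  for (j in seq_along(xs)) {
    num <- numerical_grad(function(v) {
      td_reset()
      ns <- lapply(seq_along(xs), function(k) {
        td_param(if (k == j) v else xs[[k]])
      })
      td_value(build(ns))[1]
    }, xs[[j]])
    got <- array(td_grad(nodes[[j]]), dim = dim(num))
    expect_lt(max(abs(got - num)), tol)
  }
  td_reset()
}
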