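# SE(3)-equivariant edge-state encoder.
#
# Each directed edge j->i carries a coupled pair of latent states: an
# invariant scalar channel x_ij and an equivariant tensor channel V_ij
# graded by spherical-harmonic degree l. A layer forms, per center atom i,
# a weighted projection of the atomic density around i
# (sum over neighbors k of learned weights w_ik times the geometric
# embedding of edge (i,k)), couples it with the current tensor state
# through real Clebsch-Gordan products, and re-injects invariant readouts
# of the new tensor state (degree-0 channels and per-degree norms, gated
# by the cutoff envelope) into the scalar channel through an MLP. After
# the final layer, scalar edge states are mean-pooled to atoms and then
# to residues: s_i = mean over incoming edges, z_r = mean over the
# residue's atoms.
#
# Invariance of z to rigid motions is architectural: scalars only ever
# receive rotation-invariant inputs, and tensors transform by the real
# Wigner matrices throughout.

#' Encoder configuration
#'
#' @param n_layers number of edge-update layers (>= 1).
#' @param scalar_dim width of the scalar edge channel in hidden layers.
#' @param n_channels tensor channels per degree l.
#' @param lmax maximum spherical-harmonic degree (0..3).
#' @param n_basis Bessel radial basis size.
#' @param cutoff neighborhood radius in Angstrom.
#' @param residue_dim residue token width (the final scalar MLP outputs
#'   this, so pooled tokens are residue_dim wide; 128 by convention).
#' @param node_vocab "element" or "atom37" one-hot node features.
#' @param seed integer seed for weight initialization.
#' @return an `encoder_config` list.
#' @export
encoder_config <- function(n_layers = 3L, scalar_dim = 64L,
                           n_channels = 16L, lmax = 2L, n_basis = 8L,
                           cutoff = 8, residue_dim = 128L,
                           node_vocab = c("element", "atom37"),
                           seed = 1L) {
  node_vocab <- match.arg(node_vocab)
  stopifnot(n_layers >= 1L, scalar_dim >= 1L, n_channels >= 1L,
            lmax >= 0L, lmax <= SH_LMAX_SUPPORTED, n_basis >= 1L,
            cutoff > 0, residue_dim >= 1L)
  structure(list(n_layers = as.integer(n_layers),
                 scalar_dim = as.integer(scalar_dim),
                 n_channels = as.integer(n_channels),
                 lmax = as.integer(lmax), n_basis = as.integer(n_basis),
                 cutoff = cutoff, residue_dim = as.integer(residue_dim),
                 node_vocab = node_vocab, seed = as.integer(seed)),
            class = "encoder_config")
}

# valid degree triples (l1 from V, l2 from the environment message,
# l3 output), all <= lmax
cg_paths <- function(lmax) {
  out <- list()
  for (l1 in 0:lmax) for (l2 in 0:lmax) for (l3 in 0:lmax) {
    if (l3 >= abs(l1 - l2) && l3 <= l1 + l2) {
      out[[length(out) + 1L]] <- c(l1, l2, l3)
    }
  }
  out
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, sd = sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize encoder parameters
#'
#' Deterministic given `config$seed`.
#' @param config an [encoder_config()].
#' @return named list of weight matrices.
#' @export
init_encoder_params <- function(config) {
  old <- get_rng_state(); on.exit(set_rng_state(old))
  set.seed(config$seed)
  V <- if (config$node_vocab == "element") length(ELEMENT_VOCAB) else 37L
  S <- config$scalar_dim; C <- config$n_channels
  B <- config$n_basis; lmax <- config$lmax
  inv_dim <- C * (lmax + 1L)
  p <- list()
  p$W_init <- glorot(2L * V + B, S)
  p$b_init <- matrix(0, 1, S)
  for (l in 0:lmax) p[[paste0("W_lift_", l)]] <- glorot(S, C)
  for (L in seq_len(config$n_layers)) {
    out_dim <- if (L == config$n_layers) config$residue_dim else S
    for (l in 0:lmax) {
      p[[paste0("W_wgen_", L, "_", l)]] <- glorot(S + B, C * B)
      p[[paste0("b_wgen_", L, "_", l)]] <- matrix(0, 1, C * B)
    }
    for (path in cg_paths(lmax)) {
      nm <- paste0("w_path_", L, "_", paste(path, collapse = ""))
      p[[nm]] <- matrix(stats::rnorm(C, sd = 1 / sqrt(length(cg_paths(lmax)))), 1, C)
    }
    p[[paste0("W_mlp1_", L)]] <- glorot(S + inv_dim, S)
    p[[paste0("b_mlp1_", L)]] <- matrix(0, 1, S)
    p[[paste0("W_mlp2_", L)]] <- glorot(S, out_dim)
    p[[paste0("b_mlp2_", L)]] <- matrix(0, 1, out_dim)
  }
  p
}

# wrap plain parameter arrays as tape nodes
wrap_params <- function(params, trainable = FALSE) {
  f <- if (trainable) td_param else td_const
  lapply(params, f)
}

# constant helper matrices for one degree block
block_expand <- function(C, dm) {
  # C -> C*dm column expansion (channel value copied over its m slots)
  E <- matrix(0, C, C * dm)
  for (c in seq_len(C)) E[c, (c - 1L) * dm + seq_len(dm)] <- 1
  E
}

block_sum <- function(C, dm) t(block_expand(C, dm))  # C*dm -> C column sums

y_block <- function(graph, l) {
  graph$edge_angular[, (l^2 + 1L):((l + 1L)^2), drop = FALSE]
}

#' Layer-0 edge state
#'
#' Scalar state: learned map of one-hot(center) || one-hot(neighbor) ||
#' radial basis, through SiLU. Tensor state per degree l: a learned linear
#' readout of the scalar state, expanded over channels and multiplied by
#' the degree-l spherical harmonics of the edge direction.
#'
#' @param graph a [build_local_graph()] result.
#' @param pnodes wrapped parameter nodes (see [init_encoder_params()]).
#' @param config an [encoder_config()].
#' @return edge state list with tape nodes `x` (scalar) and `V` (tensor
#'   blocks, one per degree), plus `layer = 0`.
#' @export
init_edge_state <- function(graph, pnodes, config) {
  C <- config$n_channels; lmax <- config$lmax
  oh_c <- graph$node_types[graph$edge_dst, , drop = FALSE]
  oh_n <- graph$node_types[graph$edge_src, , drop = FALSE]
  feat <- td_const(cbind(oh_c, oh_n, graph$edge_radial))
  x <- td_silu(td_linear(feat, pnodes$W_init, pnodes$b_init))
  V <- vector("list", lmax + 1L)
  for (l in 0:lmax) {
    dm <- 2L * l + 1L
    tl <- td_matmul(x, pnodes[[paste0("W_lift_", l)]])
    yrep <- y_block(graph, l)[, rep(seq_len(dm), C), drop = FALSE]
    V[[l + 1L]] <- td_mul(td_matmul(tl, td_const(block_expand(C, dm))),
                          td_const(yrep))
  }
  list(x = x, V = V, layer = 0L)
}

#' One encoder layer
#'
#' Tensor update: V_l3 <- sum over degree paths (l1,l2,l3) of learned
#' per-channel path weights times the Clebsch-Gordan coupling of V_l1
#' with the environment message M_l2 of the center atom; M is the
#' neighbor sum of w_ik-weighted geometric embeddings
#' (radial (x) angular), envelope-gated, with w_ik generated from the
#' scalar state of the reverse edge (i->k) and the radial features of
#' (i,k). Scalar update: x <- LayerNorm(MLP(\[x || invariant readout of
#' the new tensor state, envelope-gated\])).
#'
#' @param state edge state from [init_edge_state()] or a previous layer.
#' @param graph the local graph.
#' @param pnodes wrapped parameter nodes.
#' @param config an [encoder_config()].
#' @return updated edge state with `layer` incremented.
#' @export
encoder_layer <- function(state, graph, pnodes, config) {
  L <- state$layer + 1L
  if (L > config$n_layers) stop("layer index exceeds configured n_layers")
  C <- config$n_channels; B <- config$n_basis; lmax <- config$lmax
  E <- length(graph$edge_src)
  radial <- graph$edge_radial
  u <- graph$edge_envelope

  # environment messages per degree, summed per center atom
  x_rev <- td_rows(state$x, graph$reverse_edge)
  wg_in <- td_cbind(x_rev, td_const(radial))
  rrep <- radial[, rep(seq_len(B), C), drop = FALSE]  # b fast within channel
  Me <- vector("list", lmax + 1L)
  for (l in 0:lmax) {
    dm <- 2L * l + 1L
    W <- td_linear(wg_in, pnodes[[paste0("W_wgen_", L, "_", l)]],
                   pnodes[[paste0("b_wgen_", L, "_", l)]])
    tl <- td_matmul(td_mul(W, td_const(rrep)),
                    td_const(block_sum(C, B)))  # [E, C]
    yu <- y_block(graph, l)[, rep(seq_len(dm), C), drop = FALSE] * u
    msg <- td_mul(td_matmul(tl, td_const(block_expand(C, dm))),
                  td_const(yu))
    M <- td_group_sum(msg, graph$edge_dst, graph$n_atoms)
    Me[[l + 1L]] <- td_rows(M, graph$edge_dst)
  }

  # tensor product across degree paths
  Vnew <- vector("list", lmax + 1L)
  for (path in cg_paths(lmax)) {
    l1 <- path[1]; l2 <- path[2]; l3 <- path[3]
    cg <- real_cg_tensor(l1, l2, l3)
    coupled <- td_cg_couple(state$V[[l1 + 1L]], Me[[l2 + 1L]], cg, C)
    w <- pnodes[[paste0("w_path_", L, "_", paste(path, collapse = ""))]]
    wexp <- td_matmul(w, td_const(block_expand(C, 2L * l3 + 1L)))
    term <- td_bmul_row(coupled, wexp)
    Vnew[[l3 + 1L]] <- if (is.null(Vnew[[l3 + 1L]])) term else
      td_add(Vnew[[l3 + 1L]], term)
  }

  # invariant readout, envelope-gated, re-injected into the scalar channel
  inv_parts <- list(Vnew[[1L]])
  if (lmax >= 1L) {
    for (l in 1:lmax) {
      inv_parts[[l + 1L]] <- td_matmul(td_square(Vnew[[l + 1L]]),
                                       td_const(block_sum(C, 2L * l + 1L)))
    }
  }
  inv <- td_bmul_col(do.call(td_cbind, inv_parts),
                     td_const(matrix(u, ncol = 1L)))
  h <- td_silu(td_linear(td_cbind(state$x, inv),
                         pnodes[[paste0("W_mlp1_", L)]],
                         pnodes[[paste0("b_mlp1_", L)]]))
  x <- td_layernorm_rows(td_linear(h, pnodes[[paste0("W_mlp2_", L)]],
                                   pnodes[[paste0("b_mlp2_", L)]]))
  list(x = x, V = Vnew, layer = L)
}

#' Pool edge states to atoms and residues
#'
#' Two-stage arithmetic mean: s_i = mean of x over edges incoming to atom
#' i (zero vector for isolated atoms), z_r = mean of s_i over the atoms of
#' residue r.
#'
#' @param state final-layer edge state.
#' @param graph the local graph.
#' @return list with tape nodes `atom` (n_atoms x d) and `residue`
#'   (n_residues x d).
#' @export
pool_residues <- function(state, graph) {
  n_res <- max(graph$node_to_residue)
  ecount <- tabulate(graph$edge_dst, graph$n_atoms)
  s_sum <- td_group_sum(state$x, graph$edge_dst, graph$n_atoms)
  s <- td_bmul_col(s_sum, td_const(matrix(
    ifelse(ecount > 0, 1 / pmax(ecount, 1L), 0), ncol = 1L)))
  acount <- tabulate(graph$node_to_residue, n_res)
  z_sum <- td_group_sum(s, graph$node_to_residue, n_res)
  z <- td_bmul_col(z_sum, td_const(matrix(1 / acount, ncol = 1L)))
  list(atom = s, residue = z)
}

# full tape forward on a prebuilt graph with wrapped parameters
encoder_forward <- function(graph, pnodes, config) {
  if (length(graph$edge_src) == 0L) {
    n_res <- max(graph$node_to_residue)
    return(list(atom = td_const(matrix(0, graph$n_atoms, config$residue_dim)),
                residue = td_const(matrix(0, n_res, config$residue_dim))))
  }
  state <- init_edge_state(graph, pnodes, config)
  for (L in seq_len(config$n_layers)) {
    state <- encoder_layer(state, graph, pnodes, config)
  }
  pool_residues(state, graph)
}

#' Encode a structure into residue tokens
#'
#' Composition: local graph construction, layer-0 edge state, n_layers
#' equivariant edge updates, and edge -> atom -> residue mean pooling.
#' The result is invariant to rigid motions and atom-order permutations
#' of the input.
#'
#' @param structure an [all_atom_structure()] (or a prebuilt
#'   `local_graph`).
#' @param config an [encoder_config()].
#' @param params optional parameter list (default: seeded initialization
#'   from the config).
#' @param keep_atom_embeddings retain per-atom embeddings s_i.
#' @return object of class `residue_embeddings`: list with `z`
#'   (n x residue_dim matrix) and optionally `atom`.
#' @export
encode <- function(structure, config = encoder_config(), params = NULL,
                   keep_atom_embeddings = FALSE) {
  graph <- if (inherits(structure, "local_graph")) structure else
    build_local_graph(structure, cutoff = config$cutoff,
                      n_basis = config$n_basis, lmax = config$lmax,
                      node_vocab = config$node_vocab)
  if (is.null(params)) params <- init_encoder_params(config)
  td_reset()
  pn <- wrap_params(params, trainable = FALSE)
  pooled <- encoder_forward(graph, pn, config)
  out <- list(z = td_value(pooled$residue))
  if (keep_atom_embeddings) out$atom <- td_value(pooled$atom)
  out$residue_types <- if (inherits(structure, "all_atom_structure"))
    structure$residue_types else NULL
  td_reset()
  structure(out, class = "residue_embeddings")
}

#' @export
print.residue_embeddings <- function(x, ...) {
  cat("<residue_embeddings> ", nrow(x$z), " residues x ", ncol(x$z),
      " dims\n", sep = "")
  invisible(x)
}
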