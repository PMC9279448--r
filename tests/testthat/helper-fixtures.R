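# Shared fixtures and independent oracles, all built in code.

# synthetic fundus frame: bright disc of given radius in an h x w black frame
make_disc_image <- function(h, w, center_row, center_col, radius,
                            value = 0.8) {
  r <- matrix(seq_len(h), h, w)
  c <- matrix(seq_len(w), h, w, byrow = TRUE)
  d <- ((r - center_row)^2 + (c - center_col)^2 <= radius^2) * value
  array(rep(d, 3L), c(h, w, 3L))
}

# naive reference box counter: explicit double loop over grid cells
naive_box_count <- function(mask, eps) {
  n <- 0L
  for (r0 in seq(1L, nrow(mask), by = eps)) {
    for (c0 in seq(1L, ncol(mask), by = eps)) {
      cell <- mask[r0:min(r0 + eps - 1L, nrow(mask)),
                   c0:min(c0 + eps - 1L, ncol(mask)), drop = FALSE]
      if (any(cell != 0)) n <- n + 1L
    }
  }
  n
}

# Mann-Whitney pairwise-win probability (ties count 1/2): AUC oracle
mann_whitney_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  wins <- 0
  for (p in pos) for (q in neg) {
    wins <- wins + (p > q) + 0.5 * (p == q)
  }
  wins / (length(pos) * length(neg))
}

# cached default phantom (side 512) shared across test files
default_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tree <- generate_vessel_tree(tree_params(seed = 1L), 512L)
      cache <<- render_phantom(tree, seed = 1L)
    }
    cache
  }
})

small_phantom <- function(seed = 1L, side = 192L) {
  tree <- generate_vessel_tree(tree_params(seed = seed), side)
  render_phantom(tree, seed = seed)
}
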