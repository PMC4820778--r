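# fixtures and independent oracles, built in code

# point table of a Y-shaped tree: stem up z, two leaves branching at the node
y_tree_points <- function(diam = 40) {
  data.frame(x = c(0, 0, -3, 3), y = c(0, 0, 0, 0), z = c(0, 5, 9, 9),
             diameter = diam, parent = c(NA, 1, 2, 2))
}

# caterpillar: root -> node A -> node B; a leaf off A, two leaves off B
caterpillar_points <- function() {
  data.frame(
    x = c(0, 0, 2, 0, 2, -2),
    y = c(0, 0, 0, 0, 3, 3),
    z = c(0, 4, 4, 8, 8, 8),
    diameter = 30,
    parent = c(NA, 1, 2, 2, 4, 4))
}

write_swc_text <- function(lines) {
  path <- tempfile(fileext = ".swc")
  writeLines(lines, path)
  path
}

y_tree_swc <- function() {
  write_swc_text(c(
    "# a Y-shaped tree",
    "1 0 0 0 0 20 -1",
    "2 0 0 0 5 20 1",
    "3 0 -3 0 9 15 2",
    "4 0 3 0 9 15 2"))
}

# independent ordering oracle: enumerate every distal path from a branch's
# end to each reachable terminal end, count nodes passed, take the minimum
order_oracle <- function(tree) {
  br <- tree$branches
  kids <- lapply(br$branch_id, function(id) which(br$parent_id %in% id))
  min_nodes_to_leaf <- function(i) {
    if (br$ends_terminal[i]) return(0L)
    1L + min(vapply(kids[[i]], min_nodes_to_leaf, integer(1)))
  }
  setNames(vapply(seq_len(nrow(br)), min_nodes_to_leaf, integer(1)),
           br$branch_id)
}

# random rigid motion: rotation (QR of a random matrix) plus translation
apply_rigid <- function(tree, seed = 1) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  shift <- rnorm(3, sd = 100)
  xyz <- as.matrix(tree$points[, c("x", "y", "z")]) %*% t(Q)
  tree$points$x <- xyz[, 1] + shift[1]
  tree$points$y <- xyz[, 2] + shift[2]
  tree$points$z <- xyz[, 3] + shift[3]
  tree
}

# exact enumeration of all group-label assignments for small samples
# (used as the oracle null distribution of rank statistics)
enumerate_assignments <- function(sizes) {
  n <- sum(sizes)
  out <- list()
  rec <- function(remaining, groups_left, acc) {
    if (length(groups_left) == 1L) {
      out[[length(out) + 1L]] <<- c(acc, list(remaining))
      return()
    }
    take <- utils::combn(remaining, groups_left[1L], simplify = FALSE)
    for (tk in take)
      rec(setdiff(remaining, tk), groups_left[-1L], c(acc, list(tk)))
  }
  rec(seq_len(n), sizes, list())
  out
}
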