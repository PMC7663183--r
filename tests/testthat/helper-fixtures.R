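# Shared fixture builders for the test suite. Everything is generated in
# code from fixed seeds; no binary fixtures are stored.

# A deterministic gap-complete kappa V domain built from the package's own
# generator (seeded), used where a single known-good domain is enough.
fixture_fab <- function(seed = 42, n = 1) {
  make_fab_sequences(fixture_spec(n_samples = n, seed = seed))
}

# One annotated Fab pair.
fixture_annotation <- function(seed = 42) {
  fab <- fixture_fab(seed)[[1]]
  annotate_fab(fab$heavy, fab$light)
}

# Tiny 5-atom cluster with mixed elements for SASA tests.
fixture_atom_cluster <- function() {
  fab_structure(data.frame(
    name = c("C1", "N1", "O1", "S1", "C2"),
    element = c("C", "N", "O", "S", "C"),
    resname = c("A", "A", "G", "C", "L"),
    resno = c(1, 1, 2, 3, 4),
    chain = "A",
    x = c(0, 1.2, 2.8, 0.5, -1.5),
    y = c(0, 0.8, -0.5, 2.0, -1.0),
    z = c(0, -0.6, 0.4, 1.0, 1.2),
    stringsAsFactors = TRUE))
}

# Apply a rigid motion (rotation about z by theta, then translation).
rigid_move <- function(coords, theta = 0.7, shift = c(5, -3, 2)) {
  R <- matrix(c(cos(theta), -sin(theta), 0,
                sin(theta), cos(theta), 0,
                0, 0, 1), 3, 3, byrow = TRUE)
  sweep(as.matrix(coords) %*% t(R), 2, shift, "+")
}

rigid_move_structure <- function(structure, theta = 0.7, shift = c(5, -3, 2)) {
  a <- structure$atoms
  xyz <- rigid_move(a[, c("x", "y", "z")], theta, shift)
  a$x <- xyz[, 1]; a$y <- xyz[, 2]; a$z <- xyz[, 3]
  fab_structure(a)
}
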