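# programmatic fixtures shared across the suite

# full-foreground voxel block mesh of n^3 elements with the given edge (um)
block_mesh <- function(n = 4, edge = 100) {
  mask <- array(TRUE, c(n, n, n))
  attr(mask, "spacing") <- edge
  voxelize(mask, edge)
}

# beams at given unit directions, centred in the mesh interior
oriented_beams <- function(dirs, centre, half_len = 30, radius = 8) {
  n <- nrow(dirs)
  nodes <- data.frame(
    x = c(centre[1] - dirs[, 1] * half_len, centre[1] + dirs[, 1] * half_len),
    y = c(centre[2] - dirs[, 2] * half_len, centre[2] + dirs[, 2] * half_len),
    z = c(centre[3] - dirs[, 3] * half_len, centre[3] + dirs[, 3] * half_len),
    radius = radius)
  beam_mesh(nodes, data.frame(node_a = seq_len(n), node_b = n + seq_len(n),
                              source_segment = seq_len(n)))
}

random_unit_rows <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

random_rotation <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

random_symmetric3 <- function(scale = 1) {
  a <- matrix(rnorm(9, sd = scale), 3, 3)
  (a + t(a)) / 2
}

# a small vessel network with fixed topology for deterministic tests
toy_network <- function() {
  nodes <- data.frame(
    x = c(50, 150, 250, 150, 250),
    y = c(50, 60, 80, 160, 40),
    z = c(50, 55, 70, 120, 140),
    radius = c(10, 8, 6, 5, 5))
  segments <- data.frame(node_a = c(1, 2, 2, 3),
                         node_b = c(2, 3, 4, 5))
  structure(list(nodes = nodes, segments = segments,
                 metadata = list(domain_size = c(300, 300, 300))),
            class = "vessel_network")
}
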