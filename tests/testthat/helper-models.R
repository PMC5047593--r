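# Small builders shared across the suite. All fixtures are constructed in
# code; nothing is read from disk except the packaged catalogue.

# a bare model from a compact spec: one row per atom
make_model <- function(atom_name, residue_number, xyz, chain_id = "A",
                       residue_name = "ALA", b_factor = 0, label = "toy") {
  n <- length(atom_name)
  structure_model(data.frame(
    serial = seq_len(n),
    atom_name = atom_name,
    element = substr(sub("^[0-9]+", "", atom_name), 1L, 1L),
    residue_name = residue_name,
    residue_number = residue_number,
    chain_id = chain_id,
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    b_factor = b_factor,
    stringsAsFactors = FALSE), label = label)
}

# n CA-only "residues" at given coordinates (for superposition fits)
ca_model <- function(xyz, label = "ca") {
  make_model(rep("CA", nrow(xyz)), seq_len(nrow(xyz)), xyz, label = label)
}

# rotation matrix about a unit axis by angle (radians)
rot_axis <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
              3, 3, byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# random proper rotation
random_rotation <- function() {
  rot_axis(stats::rnorm(3), stats::runif(1, 0, 2 * pi))
}

apply_rigid <- function(model, R, t_vec) {
  xyz <- coords(model) %*% t(R)
  xyz <- sweep(xyz, 2L, t_vec, `+`)
  m <- model
  m$atoms$x <- xyz[, 1L]; m$atoms$y <- xyz[, 2L]; m$atoms$z <- xyz[, 3L]
  m
}

# wild-type Asp and mutant Asn side chains at residue 45, embedded in a
# short common scaffold so the fit has enough C-alpha atoms
asp_asn_pair <- function() {
  scaffold <- function(extra_names, extra_res, extra_xyz, resname) {
    base_names <- rep(c("N", "CA", "C", "O"), 4)
    base_res <- rep(c(43L, 44L, 46L, 47L), each = 4)
    base_xyz <- cbind(seq_len(16) * 1.7,
                      rep(c(0, 1.2, 0.4, -0.8), 4),
                      rep(c(0.3, -0.5, 1.1, 0), each = 4))
    make_model(c(base_names, extra_names),
               c(base_res, extra_res),
               rbind(base_xyz, extra_xyz),
               residue_name = resname)
  }
  res45 <- cbind(30 + seq_len(8) * 0.9, seq_len(8) * 0.5, -seq_len(8) * 0.3)
  wt <- scaffold(c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
                 rep(45L, 8), res45, "ASP")
  mut <- scaffold(c("N", "CA", "C", "O", "CB", "CG", "OD1", "ND2"),
                  rep(45L, 8), res45, "ASN")
  list(wt = wt, mut = mut)
}
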