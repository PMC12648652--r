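# Shared test helpers: small block sets and independent oracles.

# fixture substituent templates, duplicated here so tests predict product
# structures without going through the reaction code
fixture_amine_smi <- function(subs) sprintf("Nc1cncc(%s)n1", subs)
fixture_sulfonyl_smi <- function(subs) {
  sprintf("O=S(=O)(Cl)c1ccc(%s)cc1", subs)
}

# template-level oracle: the product of fixture blocks, written directly
# as SMILES (independent of the reaction graph edit)
fixture_product_smi <- function(amine_sub, sulfonyl_sub) {
  sprintf("O=S(=O)(Nc1cncc(%s)n1)c1ccc(%s)cc1", amine_sub, sulfonyl_sub)
}

# brute-force nested-loop enumeration oracle over fixture substituents:
# canonical product multiset from the SMILES templates
oracle_library <- function(amine_subs, sulfonyl_subs) {
  prods <- as.vector(outer(amine_subs, sulfonyl_subs,
                           Vectorize(fixture_product_smi)))
  sort(canon_smiles(prods))
}

load_fixture_blocks <- function(n_amines, n_sulfonyls, dir = tempdir()) {
  fx <- gen_blocks(n_amines, n_sulfonyls, dir = dir)
  list(
    amines = load_blocks(fx$amine_file, role_hint = "amino_heteroarene"),
    sulfonyls = load_blocks(fx$sulfonyl_file,
                            role_hint = "sulfonyl_chloride"),
    fx = fx
  )
}

# random rigid motion (rotation + translation) applied to a coordinate
# matrix
random_rigid_motion <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  R <- matrix(c(
    1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]),
    2 * (q[2] * q[4] + q[1] * q[3]),
    2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
    2 * (q[3] * q[4] - q[1] * q[2]),
    2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]),
    1 - 2 * (q[2]^2 + q[3]^2)
  ), 3L, 3L, byrow = TRUE)
  t <- stats::rnorm(3, sd = 10)
  list(R = R, t = t)
}

apply_motion_mol <- function(mol, motion) {
  xyz <- as.matrix(mol$atoms[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2L, motion$t, `+`)
  mol$atoms$x <- xyz[, 1L]; mol$atoms$y <- xyz[, 2L]
  mol$atoms$z <- xyz[, 3L]
  mol
}

apply_motion_receptor <- function(receptor, motion) {
  xyz <- as.matrix(receptor$atoms[, c("x", "y", "z")]) %*% t(motion$R)
  xyz <- sweep(xyz, 2L, motion$t, `+`)
  receptor$atoms$x <- xyz[, 1L]; receptor$atoms$y <- xyz[, 2L]
  receptor$atoms$z <- xyz[, 3L]
  receptor
}

# canonical sort of a contact table for set comparison
contact_key <- function(contacts) {
  sort(sprintf("%s|%s|%d", contacts$kind, contacts$resname,
               contacts$resnum))
}

# boundary fixture with exactly representable coordinates (PDB stores 3
# decimals): one apolar receptor carbon at (dist, 0, 0) and an ethane
# carbon pair at the origin
boundary_fixture <- function(dist) {
  f <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = f, xyz = c(dist, 0, 0, dist + 1.54, 0, 0),
                   resno = c(236L, 236L), resid = c("LEU", "LEU"),
                   elety = c("CD1", "CD2"), chain = c("A", "A"),
                   eleno = 1:2)
  lig <- focuslib:::.fl_mol(
    data.frame(elem = c("C", "C"), chg = 0L,
               x = c(0, -1.54), y = 0, z = 0),
    data.frame(a1 = 1L, a2 = 2L, order = 1L), "ethane_probe")
  list(receptor = read_receptor(f), ligand = lig)
}

# the generator's substituent palette (the enumeration oracle combines it
# through SMILES templates, independently of the reaction code)
.substituent_palette_test <- function(n) focuslib:::.substituent_palette(n)

# directory holding the study's deposited data package, when a copy has
# been placed there manually (replication tests require it)
deposited_data_dir <- function() {
  getOption("focuslib.deposited_dir",
            file.path("..", "deposited_data"))
}
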