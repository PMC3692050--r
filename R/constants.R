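#' Pipeline defaults and documented constants
#'
#' Single table of the constants that define the modeling protocol: the
#' replica count, default temperature ranges for the two modes, the GDT_TS
#' gate separating the two consensus restraint regimes, the average-RMSD
#' threshold of the representative-selection rule, the sequence-length cap
#' and the recommended de novo length.
#'
#' @format A named list.
#' @export
fold_defaults <- list(
  max_seq_length    = 900L,   # hard cap on query length (residues)
  denovo_length_rec = 120L,   # above this, de novo mode draws a warning
  n_replicas        = 20L,
  t_denovo          = c(3.5, 1.0),
  t_consensus       = c(2.0, 1.0),
  gdt_gate          = 0.3,    # min pairwise template GDT_TS for min/max regime
  rep_rmsd_switch   = 2.15,   # Angstrom; above -> medoid, else average structure
  bond_length       = 3.8,    # virtual Ca-Ca bond (Angstrom)
  bond_window       = c(3.4, 4.2),
  clash_dist        = 4.0,    # hard-core distance for non-adjacent beads
  s_min             = 5L,     # minimum |i - j| for an automatic restraint
  d_cap             = 25,     # Angstrom; pairs with larger mean distance skipped
  tau               = 1.0,    # single-template restraint half-width (Angstrom)
  sigma_floor       = 3.0,    # lower bound applied to distribution-regime dmin
  restraint_weight  = 1.0,
  k_clusters        = 10L,
  n_models          = 5L
)

aa1 <- c("A","R","N","D","C","Q","E","G","H","I",
         "L","K","M","F","P","S","T","W","Y","V")

aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
         Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
         L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
         S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

# surrogate internal-energy parameters (model units); see the methods vignette
energy_defaults <- list(
  k_bond   = 10,      # per Angstrom^2, harmonic about bond_length
  k_angle  = 5,       # per radian^2, pseudo-bond-angle bias for H/E states
  theta_H  = 91 * pi / 180,   # Ca pseudo-angle target, helix
  theta_E  = 120 * pi / 180,  # Ca pseudo-angle target, extended
  k_rep    = 10       # per Angstrom^2, soft core below clash_dist
)

move_defaults <- list(
  p_single   = 0.6,  p_crank = 0.3, p_pivot = 0.1,
  max_disp   = 0.7,           # Angstrom, single-bead displacement radius
  max_angle  = 30 * pi / 180  # crankshaft / pivot rotation half-range
)
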