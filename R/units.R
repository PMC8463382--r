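# Physical constants and unit conversions used across the package.
# Internal conventions: densities live on Bohr grids in e/Bohr^3; structure
# coordinates are Angstrom on input (PDB) and nm in reported tables; bonded
# parameters are kJ/mol nm^2 under the E = K_r (r - r0)^2 convention.

#' Unit conversion constants
#'
#' Named constants used throughout: `bohr_A` (1 Bohr in Angstrom),
#' `hartree_kJmol` (1 Hartree in kJ/mol) and `hb2_kJmolnm2`
#' (1 Hartree/Bohr^2 in kJ/mol nm^2, the force-constant conversion).
#'
#' @return A named numeric vector.
#' @examples
#' neet_constants()["bohr_A"]
#' @export
neet_constants <- function() {
  bohr_A <- 0.529177210903
  hartree_kJmol <- 2625.4996394799
  c(
    bohr_A = bohr_A,
    A_bohr = 1 / bohr_A,
    nm_bohr = 10 / bohr_A,
    hartree_kJmol = hartree_kJmol,
    # 1 Hartree/Bohr^2 expressed in kJ/mol nm^2
    hb2_kJmolnm2 = hartree_kJmol / (bohr_A / 10)^2
  )
}

.BOHR_A <- 0.529177210903
.HARTREE_KJMOL <- 2625.4996394799
.HB2_KJMOLNM2 <- .HARTREE_KJMOL / (.BOHR_A / 10)^2
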