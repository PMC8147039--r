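# Periodic table symbols plus the "Zz" pseudo-element (generic placeholder
# atom used e.g. to mark where polymer repeat units join).

ELEMENT_SYMBOLS <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca",
  "Sc", "Ti", "V", "Cr", "Mn", "Fe", "Co", "Ni", "Cu", "Zn",
  "Ga", "Ge", "As", "Se", "Br", "Kr", "Rb", "Sr", "Y", "Zr",
  "Nb", "Mo", "Tc", "Ru", "Rh", "Pd", "Ag", "Cd", "In", "Sn",
  "Sb", "Te", "I", "Xe", "Cs", "Ba", "La", "Ce", "Pr", "Nd",
  "Pm", "Sm", "Eu", "Gd", "Tb", "Dy", "Ho", "Er", "Tm", "Yb",
  "Lu", "Hf", "Ta", "W", "Re", "Os", "Ir", "Pt", "Au", "Hg",
  "Tl", "Pb", "Bi", "Po", "At", "Rn", "Fr", "Ra", "Ac", "Th",
  "Pa", "U", "Np", "Pu", "Am", "Cm", "Bk", "Cf", "Es", "Fm",
  "Md", "No", "Lr", "Rf", "Db", "Sg", "Bh", "Hs", "Mt", "Ds",
  "Rg", "Cn", "Nh", "Fl", "Mc", "Lv", "Ts", "Og"
)

ALL_SYMBOLS <- c(ELEMENT_SYMBOLS, "Zz")

# Default valences used to fill implicit hydrogens. A formal charge of +/-1
# shifts the effective valence by the charge (N+ binds 4, O- binds 1).
# Elements absent from this table (metals, noble gases, ...) get no implicit
# hydrogens and are accepted silently.
DEFAULT_VALENCE <- c(
  H = 1, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1, B = 3, Si = 4, Zz = 1
)

is_known_symbol <- function(sym) sym %in% ALL_SYMBOLS

# Global element ordering used both for Hill formulas (after C and H) and for
# the canonical index convention: carbon block first, heteroatoms
# alphabetically, Zz after every true element.
element_rank <- function(sym) {
  r <- match(sym, sort(ELEMENT_SYMBOLS))
  r[sym == "C"] <- 0L
  r[sym == "Zz"] <- length(ELEMENT_SYMBOLS) + 1L
  if (anyNA(r)) argument_error("element", paste("unknown element:", sym[is.na(r)][1]))
  r
}

default_valence <- function(sym, charge = 0L) {
  v <- unname(DEFAULT_VALENCE[sym])
  v[is.na(v)] <- NA_real_
  eff <- v + charge
  eff[!is.na(eff) & eff < 0] <- 0
  eff
}
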