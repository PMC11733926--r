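#' Element property table
#'
#' A small periodic-table lookup embedded in the package so that
#' element-property descriptor statistics require no external database at
#' run time. Covers the elements that occur in drug-like organic chemistry
#' (H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I plus the common metals seen in
#' salts). Properties: IUPAC group number (1-18), period, standard atomic
#' mass (u), Pauling electronegativity, melting point (K), covalent radius
#' (pm), first ionization energy (eV) and number of valence electrons.
#'
#' @return A data.frame with one row per element, rownames = element symbol.
#' @export
element_properties <- function() {
  tab <- data.frame(
    symbol = c("H","B","C","N","O","F","Na","Mg","Al","Si","P","S","Cl",
               "K","Ca","Fe","Cu","Zn","Se","Br","I"),
    group  = c(1, 13, 14, 15, 16, 17, 1, 2, 13, 14, 15, 16, 17,
               1, 2, 8, 11, 12, 16, 17, 17),
    period = c(1, 2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 3, 3,
               4, 4, 4, 4, 4, 4, 4, 5),
    mass   = c(1.008, 10.81, 12.011, 14.007, 15.999, 18.998, 22.990, 24.305,
               26.982, 28.085, 30.974, 32.06, 35.45, 39.098, 40.078, 55.845,
               63.546, 65.38, 78.971, 79.904, 126.904),
    electronegativity = c(2.20, 2.04, 2.55, 3.04, 3.44, 3.98, 0.93, 1.31,
                          1.61, 1.90, 2.19, 2.58, 3.16, 0.82, 1.00, 1.83,
                          1.90, 1.65, 2.55, 2.96, 2.66),
    melting_point = c(13.99, 2349, 3823, 63.15, 54.36, 53.48, 370.87, 923,
                      933.47, 1687, 317.3, 388.36, 171.6, 336.53, 1115,
                      1811, 1357.77, 692.68, 494, 265.8, 386.85),
    covalent_radius = c(31, 84, 76, 71, 66, 57, 166, 141, 121, 111, 107,
                        105, 102, 203, 176, 132, 132, 122, 120, 120, 139),
    ionization_energy = c(13.598, 8.298, 11.260, 14.534, 13.618, 17.423,
                          5.139, 7.646, 5.986, 8.152, 10.487, 10.360,
                          12.968, 4.341, 6.113, 7.902, 7.726, 9.394,
                          9.752, 11.814, 10.451),
    valence_electrons = c(1, 3, 4, 5, 6, 7, 1, 2, 3, 4, 5, 6, 7,
                          1, 2, 8, 11, 12, 6, 7, 7),
    stringsAsFactors = FALSE
  )
  rownames(tab) <- tab$symbol
  tab
}

# Elements enumerated by the element-fraction block. A fixed, ordered list so
# the block has a stable width regardless of the molecules featurized.
.element_fraction_symbols <- c(
  "H","He","Li","Be","B","C","N","O","F","Ne","Na","Mg","Al","Si","P","S",
  "Cl","Ar","K","Ca","Sc","Ti","V","Cr","Mn","Fe","Co","Ni","Cu","Zn","Ga",
  "Ge","As","Se","Br","Kr","Rb","Sr","Y","Zr","Nb","Mo","Tc","Ru","Rh","Pd",
  "Ag","Cd","In","Sn","Sb","Te","I","Xe","Cs","Ba","La","Ce","Pr","Nd","Sm",
  "Eu","Gd","Tb","Dy","Ho","Er","Tm","Yb","Lu","Hf","Ta","W","Re","Os","Ir",
  "Pt","Au","Hg","Tl","Pb","Bi","Th","U")

# default valences used to infer implicit hydrogen counts from a kekulized
# connection table (charge-adjusted for the common N+/O-/S+ cases)
.default_valence <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Se = 2, Br = 1, I = 1)
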