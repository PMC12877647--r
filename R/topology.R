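# Ideal internal-coordinate topology for side-chain heavy atoms beyond CB.
# Each atom is placed by NeRF from three stem atoms (a, b, c; c is the
# bonded parent): bond |c-d|, angle b-c-d, dihedral a-b-c-d. The dihedral is
# either chi_k (+ a fixed offset, for branch/planar atoms) or an absolute
# value when chi is NA. Bond lengths/angles are standard ideal values;
# five/six-membered rings are built atom-by-atom on the ring plane.

sc_atom <- function(name, a, b, c, bond, angle, chi = NA_integer_, off = 0) {
  data.frame(name = name, a = a, b = b, c = c, bond = bond, angle = angle,
             chi = as.integer(chi), off = off, stringsAsFactors = FALSE)
}

sidechain_topology <- local({
  topo <- NULL
  function() {
    if (!is.null(topo)) return(topo)
    t <- list(
      ALA = NULL,
      GLY = NULL,
      SER = rbind(sc_atom("OG", "N", "CA", "CB", 1.42, 110.8, 1)),
      CYS = rbind(sc_atom("SG", "N", "CA", "CB", 1.81, 114.0, 1)),
      THR = rbind(sc_atom("OG1", "N", "CA", "CB", 1.43, 109.5, 1),
                  sc_atom("CG2", "N", "CA", "CB", 1.53, 110.5, 1, -122)),
      VAL = rbind(sc_atom("CG1", "N", "CA", "CB", 1.53, 110.5, 1),
                  sc_atom("CG2", "N", "CA", "CB", 1.53, 110.5, 1, 122)),
      ILE = rbind(sc_atom("CG1", "N", "CA", "CB", 1.53, 110.4, 1),
                  sc_atom("CG2", "N", "CA", "CB", 1.53, 110.5, 1, -122),
                  sc_atom("CD1", "CA", "CB", "CG1", 1.53, 113.8, 2)),
      LEU = rbind(sc_atom("CG", "N", "CA", "CB", 1.53, 116.3, 1),
                  sc_atom("CD1", "CA", "CB", "CG", 1.53, 110.5, 2),
                  sc_atom("CD2", "CA", "CB", "CG", 1.53, 110.5, 2, 122)),
      MET = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 114.0, 1),
                  sc_atom("SD", "CA", "CB", "CG", 1.80, 112.7, 2),
                  sc_atom("CE", "CB", "CG", "SD", 1.79, 100.9, 3)),
      PHE = rbind(sc_atom("CG", "N", "CA", "CB", 1.50, 113.8, 1),
                  sc_atom("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
                  sc_atom("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
                  sc_atom("CE1", "CB", "CG", "CD1", 1.39, 120.0, NA, 180),
                  sc_atom("CE2", "CB", "CG", "CD2", 1.39, 120.0, NA, 180),
                  sc_atom("CZ", "CG", "CD1", "CE1", 1.39, 120.0, NA, 0)),
      TYR = rbind(sc_atom("CG", "N", "CA", "CB", 1.50, 113.8, 1),
                  sc_atom("CD1", "CA", "CB", "CG", 1.39, 120.8, 2),
                  sc_atom("CD2", "CA", "CB", "CG", 1.39, 120.8, 2, 180),
                  sc_atom("CE1", "CB", "CG", "CD1", 1.39, 120.0, NA, 180),
                  sc_atom("CE2", "CB", "CG", "CD2", 1.39, 120.0, NA, 180),
                  sc_atom("CZ", "CG", "CD1", "CE1", 1.39, 120.0, NA, 0),
                  sc_atom("OH", "CD1", "CE1", "CZ", 1.38, 119.9, NA, 180)),
      TRP = rbind(sc_atom("CG", "N", "CA", "CB", 1.50, 113.6, 1),
                  sc_atom("CD1", "CA", "CB", "CG", 1.37, 127.0, 2),
                  sc_atom("CD2", "CA", "CB", "CG", 1.43, 126.6, 2, 180),
                  sc_atom("NE1", "CB", "CG", "CD1", 1.38, 110.2, NA, 180),
                  sc_atom("CE2", "CB", "CG", "CD2", 1.40, 107.2, NA, 180),
                  sc_atom("CE3", "CB", "CG", "CD2", 1.40, 133.9, NA, 0),
                  sc_atom("CZ2", "CG", "CD2", "CE2", 1.40, 122.4, NA, 180),
                  sc_atom("CZ3", "CG", "CD2", "CE3", 1.39, 118.8, NA, 180),
                  sc_atom("CH2", "CD2", "CE3", "CZ3", 1.37, 121.1, NA, 0)),
      HIS = rbind(sc_atom("CG", "N", "CA", "CB", 1.49, 113.8, 1),
                  sc_atom("ND1", "CA", "CB", "CG", 1.38, 122.7, 2),
                  sc_atom("CD2", "CA", "CB", "CG", 1.36, 131.1, 2, 180),
                  sc_atom("CE1", "CB", "CG", "ND1", 1.32, 109.2, NA, 180),
                  sc_atom("NE2", "CB", "CG", "CD2", 1.37, 107.2, NA, 180)),
      ASP = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 112.6, 1),
                  sc_atom("OD1", "CA", "CB", "CG", 1.25, 118.5, 2),
                  sc_atom("OD2", "CA", "CB", "CG", 1.25, 118.5, 2, 180)),
      ASN = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 112.6, 1),
                  sc_atom("OD1", "CA", "CB", "CG", 1.23, 120.8, 2),
                  sc_atom("ND2", "CA", "CB", "CG", 1.33, 116.4, 2, 180)),
      GLU = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                  sc_atom("CD", "CA", "CB", "CG", 1.52, 112.6, 2),
                  sc_atom("OE1", "CB", "CG", "CD", 1.25, 118.5, 3),
                  sc_atom("OE2", "CB", "CG", "CD", 1.25, 118.5, 3, 180)),
      GLN = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                  sc_atom("CD", "CA", "CB", "CG", 1.52, 112.6, 2),
                  sc_atom("OE1", "CB", "CG", "CD", 1.23, 120.8, 3),
                  sc_atom("NE2", "CB", "CG", "CD", 1.33, 116.4, 3, 180)),
      LYS = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                  sc_atom("CD", "CA", "CB", "CG", 1.52, 111.3, 2),
                  sc_atom("CE", "CB", "CG", "CD", 1.52, 111.3, 3),
                  sc_atom("NZ", "CG", "CD", "CE", 1.47, 112.0, 4)),
      ARG = rbind(sc_atom("CG", "N", "CA", "CB", 1.52, 114.1, 1),
                  sc_atom("CD", "CA", "CB", "CG", 1.52, 111.3, 2),
                  sc_atom("NE", "CB", "CG", "CD", 1.46, 112.0, 3),
                  sc_atom("CZ", "CG", "CD", "NE", 1.33, 124.2, 4),
                  sc_atom("NH1", "CD", "NE", "CZ", 1.33, 120.0, NA, 0),
                  sc_atom("NH2", "CD", "NE", "CZ", 1.33, 120.0, NA, 180)),
      PRO = rbind(sc_atom("CG", "N", "CA", "CB", 1.50, 104.5, 1),
                  sc_atom("CD", "CA", "CB", "CG", 1.51, 106.1, 2))
    )
    topo <<- t
    topo
  }
})

# number of chi angles per residue type (three-letter code)
n_chi <- function(resid) {
  tp <- sidechain_topology()[[resid]]
  if (is.null(tp)) 0L else max(0L, tp$chi, na.rm = TRUE)
}

# chi rotation axes: list of c(atom_b, atom_c) per chi, derived from the
# placement row of the atom that defines chi k (offset 0)
chi_axes <- function(resid) {
  tp <- sidechain_topology()[[resid]]
  if (is.null(tp)) return(list())
  k <- n_chi(resid)
  lapply(seq_len(k), function(i) {
    row <- tp[!is.na(tp$chi) & tp$chi == i & tp$off == 0, ][1, ]
    c(row$b, row$c)
  })
}

# atoms moved by rotating chi k: descendants of the axis atom c under the
# bonded-parent relation (parent = stem c), plus same-chi branch atoms
chi_movable <- function(resid, k) {
  tp <- sidechain_topology()[[resid]]
  if (is.null(tp)) return(character(0))
  axis_c <- chi_axes(resid)[[k]][2]
  parent <- stats::setNames(tp$c, tp$name)
  desc <- function(atom) {
    kids <- tp$name[tp$c == atom]
    c(kids, unlist(lapply(kids, desc)))
  }
  if (axis_c == "CB") {
    # chi1 moves every side-chain atom beyond CB
    tp$name
  } else {
    unique(desc(axis_c))
  }
}

# element symbol from a side-chain atom name
element_from_name <- function(name) {
  toupper(substr(gsub("^[0-9]+", "", name), 1, 1))
}

# ideal CB position from backbone N, CA, C (L-configuration)
ideal_cb <- function(N, CA, C) {
  place_atom(C, N, CA, 1.53, 110.5, -122.6)
}
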