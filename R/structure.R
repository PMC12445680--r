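#' @useDynLib redoxpb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats approx coef dist lm runif setNames uniroot
#' @importFrom utils read.csv write.csv
NULL

#' Construct a charged molecular structure
#'
#' The central container of the package: an ordered atom table with
#' coordinates (Angstrom), partial charges (elementary charges) and radii
#' (Angstrom), optional alternative conformers sharing the same atom ordering,
#' and an optional declaration of the membrane interface planes along the
#' +z membrane normal.
#'
#' @param atoms data.frame with columns \code{atom_id}, \code{atom_name},
#'   \code{residue_name}, \code{chain_id}, \code{residue_number},
#'   \code{x}, \code{y}, \code{z}, \code{charge}, \code{radius}.
#' @param conformers optional list of n_atoms x 3 coordinate matrices, same
#'   atom ordering as \code{atoms}.
#' @param z_interfaces optional numeric(2), z of the two membrane/solvent
#'   interface planes in Angstrom (user-declared; the membrane normal is +z).
#' @return object of class \code{pb_structure}
#' @export
pb_structure <- function(atoms, conformers = NULL, z_interfaces = NULL) {
  need <- c("atom_id", "atom_name", "residue_name", "chain_id",
            "residue_number", "x", "y", "z", "charge", "radius")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table missing columns: ", paste(miss, collapse = ", "))
  atoms <- as.data.frame(atoms)[, need]
  if (any(!is.finite(atoms$x)) || any(!is.finite(atoms$y)) ||
      any(!is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  if (any(!is.finite(atoms$charge))) stop("non-finite atom charges")
  if (any(!is.finite(atoms$radius)) || any(atoms$radius < 0))
    stop("atom radii must be finite and >= 0")
  if (!is.null(conformers)) {
    for (k in seq_along(conformers)) {
      m <- conformers[[k]]
      if (!is.matrix(m) || nrow(m) != nrow(atoms) || ncol(m) != 3)
        stop("conformer ", k, " does not match base atom count/ordering")
    }
  }
  structure(list(atoms = atoms, conformers = conformers,
                 z_interfaces = z_interfaces),
            class = "pb_structure")
}

#' @export
print.pb_structure <- function(x, ...) {
  a <- x$atoms
  cat("pb_structure:", nrow(a), "atoms,",
      length(unique(paste(a$chain_id, a$residue_number))), "residues, net charge",
      sprintf("%+.3f e", sum(a$charge)))
  if (!is.null(x$conformers))
    cat(",", length(x$conformers), "conformers")
  cat("\n")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param structure a \code{pb_structure}
#' @param conformer NULL for the base coordinates, or a conformer index
#' @return n x 3 numeric matrix
#' @export
atom_coords <- function(structure, conformer = NULL) {
  if (is.null(conformer))
    return(cbind(x = structure$atoms$x, y = structure$atoms$y,
                 z = structure$atoms$z))
  if (is.null(structure$conformers) || conformer > length(structure$conformers))
    stop("conformer ", conformer, " not present")
  m <- structure$conformers[[conformer]]
  colnames(m) <- c("x", "y", "z")
  m
}

#' Replace base coordinates with those of a conformer
#' @inheritParams atom_coords
#' @return a \code{pb_structure} with the conformer's coordinates and no
#'   conformer list (atom ordering is never changed)
#' @export
use_conformer <- function(structure, conformer) {
  m <- atom_coords(structure, conformer)
  structure$atoms$x <- m[, 1]
  structure$atoms$y <- m[, 2]
  structure$atoms$z <- m[, 3]
  structure$conformers <- NULL
  structure
}

#' Read a PQR file
#'
#' Whitespace-delimited PQR dialect: ATOM/HETATM records carrying per-atom
#' partial charge and radius as the last two numeric fields.  Both the
#' 10-field (no chain id) and 11-field (with chain id) layouts are accepted.
#'
#' @param path file path
#' @return a \code{pb_structure}, atoms in file order
#' @export
read_pqr <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  idx <- which(keep)
  if (length(idx) == 0) stop("no ATOM/HETATM records in ", path)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    f <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(f) == 11) {
      chain <- f[5]; off <- 0
    } else if (length(f) == 10) {
      chain <- "A"; off <- -1
    } else {
      stop("line ", ln, ": expected 10 or 11 whitespace-delimited fields, got ",
           length(f))
    }
    num <- suppressWarnings(as.numeric(f[c(2, 6, 7, 8, 9, 10, 11) + off]))
    if (any(is.na(num)))
      stop("line ", ln, ": malformed numeric field (serial/resSeq/x/y/z/charge/radius)")
    rows[[k]] <- data.frame(
      atom_id = as.integer(num[1]), atom_name = f[3], residue_name = f[4],
      chain_id = chain, residue_number = as.integer(num[2]),
      x = num[3], y = num[4], z = num[5], charge = num[6], radius = num[7],
      stringsAsFactors = FALSE)
  }
  pb_structure(do.call(rbind, rows))
}

#' Write a PQR file
#'
#' Emits the 11-field whitespace dialect read back by \code{\link{read_pqr}};
#' charges and radii are printed to 4 decimals, coordinates to 3.
#'
#' @param structure a \code{pb_structure}
#' @param path output path
#' @export
write_pqr <- function(structure, path) {
  a <- structure$atoms
  lines <- sprintf("ATOM %d %s %s %s %d %.3f %.3f %.3f %.4f %.4f",
                   a$atom_id, a$atom_name, a$residue_name, a$chain_id,
                   a$residue_number, a$x, a$y, a$z, a$charge, a$radius)
  writeLines(lines, path)
  invisible(path)
}

#' Bundled amino-acid model-compound charge/radius library
#'
#' A deliberately simple synthetic parameter set: heavy atoms only,
#' element-based radii, and the formal charge of each ionizable group
#' distributed over its terminal atoms.  It is a stand-in for force-field
#' charge sets (which are out of scope here); per-state charges of titratable
#' groups live in \code{\link{titration_states_table}}.
#'
#' @return data.frame with columns residue, atom, charge, radius
#' @export
charge_library <- function() {
  path <- system.file("extdata", "charge_library.csv", package = "redoxpb")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Bundled per-state charges of titratable groups
#'
#' For each titratable residue type: the charge states sampled in titration,
#' the atoms carrying state-dependent charge, and the reference pKa (Arg 12.0,
#' Asp 4.0, Cys 9.5, Glu 4.4, Lys 10.4, Tyr 9.6; His as a 3-state tautomer
#' site with N-epsilon 7.0 and N-delta 6.6) or reference Em (Trp/Trp+. 1070 mV
#' in water).  The Trp radical-cation charge distribution is a synthetic
#' stand-in (the published set belongs to prior work and is not reproduced).
#'
#' @return data.frame with columns residue, kind, state, atom, charge
#' @export
titration_states_table <- function() {
  path <- system.file("extdata", "titratable_states.csv", package = "redoxpb")
  read.csv(path, stringsAsFactors = FALSE)
}

#' Reference pKa / Em values used for titratable sites
#' @return named list: pKa per residue type (His has two values, for the
#'   N-epsilon and N-delta protons) and Em_mV for the Trp radical cation
#' @export
reference_values <- function() {
  list(ASP = 4.0, GLU = 4.4, CYS = 9.5, TYR = 9.6, LYS = 10.4, ARG = 12.0,
       HIS = c(Ne = 7.0, Nd = 6.6), TRP_Em_mV = 1070)
}

#' Read a PDB file and assign charges/radii from the bundled library
#'
#' Coordinates are parsed with \pkg{bio3d}; hydrogens are dropped, and all
#' waters are removed except those named in \code{keep_waters} (retained
#' ligand waters).  Charges and radii come from the bundled model-compound
#' library; residues absent from the library are an error unless
#' \code{zero_charge_fallback} is TRUE (then charge 0, element radius).
#'
#' @param path PDB file path
#' @param keep_waters character vector of "chain:resno" water identifiers to
#'   retain (e.g. \code{"A:501"})
#' @param zero_charge_fallback logical; permit unknown residues with zero
#'   charge and element-based radii
#' @param library charge/radius table, default \code{\link{charge_library}()}
#' @return a \code{pb_structure}
#' @export
read_pdb <- function(path, keep_waters = character(),
                     zero_charge_fallback = FALSE,
                     library = charge_library()) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  # drop hydrogens
  a <- a[!grepl("^[0-9]*H", trimws(a$elety)), , drop = FALSE]
  water <- a$resid %in% c("HOH", "WAT", "TIP", "SOL")
  keep_id <- paste(a$chain, a$resno, sep = ":")
  a <- a[!water | keep_id[seq_len(nrow(a))] %in% keep_waters, , drop = FALSE]
  unknown <- setdiff(unique(a$resid), c(unique(library$residue), "HOH", "WAT"))
  if (length(unknown) > 0 && !zero_charge_fallback)
    stop("residues absent from charge library (set zero_charge_fallback=TRUE ",
         "to keep them uncharged): ", paste(unknown, collapse = ", "))
  key <- paste(a$resid, trimws(a$elety))
  lib_key <- paste(library$residue, library$atom)
  hit <- match(key, lib_key)
  q <- ifelse(is.na(hit), 0, library$charge[hit])
  r <- ifelse(is.na(hit), element_radius(trimws(a$elety)), library$radius[hit])
  ch <- ifelse(is.na(a$chain) | a$chain == "", "A", a$chain)
  pb_structure(data.frame(
    atom_id = seq_len(nrow(a)), atom_name = trimws(a$elety),
    residue_name = a$resid, chain_id = ch, residue_number = a$resno,
    x = a$x, y = a$y, z = a$z, charge = q, radius = r,
    stringsAsFactors = FALSE))
}

# Bondi-style radii keyed on the leading element letter of an atom name.
element_radius <- function(atom_name) {
  first <- substr(gsub("^[0-9]+", "", atom_name), 1, 1)
  r <- c(C = 1.7, N = 1.55, O = 1.52, S = 1.8, P = 1.8, H = 1.2, F = 1.47)
  out <- unname(r[first])
  out[is.na(out)] <- 1.7
  out
}

#' Define a titratable site
#'
#' @param site_id text identifier
#' @param kind one of "acid", "base", "his_tautomer", "redox"
#' @param member_atoms integer indices into the structure's atom table
#' @param state_charges numeric matrix, one row per charge state in titration
#'   order (adjacent rows differ by exactly one proton or one electron, i.e.
#'   +-1 total charge), one column per member atom; row 1 is the reference
#'   state (deprotonated for acid/base, N-epsilon tautomer for His, reduced
#'   for redox)
#' @param reference reference pKa (acid/base), named numeric c(Ne=,Nd=) for
#'   His, or reference Em in mV (redox)
#' @param fixed_state optional state label to clamp the site to
#' @return object of class \code{titratable_site}
#' @export
titratable_site <- function(site_id, kind, member_atoms, state_charges,
                            reference, fixed_state = NULL) {
  kind <- match.arg(kind, c("acid", "base", "his_tautomer", "redox"))
  if (!is.matrix(state_charges) || nrow(state_charges) < 2)
    stop("state_charges must be a matrix with >= 2 state rows")
  if (ncol(state_charges) != length(member_atoms))
    stop("state_charges columns must match member_atoms")
  tot <- rowSums(state_charges)
  if (any(abs(abs(diff(tot)) - 1) > 1e-6))
    stop("adjacent states must differ by exactly +-1 total elementary charge")
  n_trans <- nrow(state_charges) - 1
  if (length(reference) != n_trans && !(kind == "redox" && length(reference) == 1))
    stop("need one reference value per state transition")
  if (!is.null(fixed_state) &&
      !fixed_state %in% rownames(state_charges))
    stop("fixed_state '", fixed_state, "' is not a state of site ", site_id)
  structure(list(site_id = site_id, kind = kind,
                 member_atoms = as.integer(member_atoms),
                 state_charges = state_charges,
                 reference = reference, fixed_state = fixed_state),
            class = "titratable_site")
}

#' State-difference charges of a site relative to its reference state
#' @param site a \code{titratable_site}
#' @param state state row index or label (default: second state)
#' @return numeric vector over member atoms
#' @export
site_delta_charges <- function(site, state = 2) {
  if (is.character(state)) state <- match(state, rownames(site$state_charges))
  site$state_charges[state, ] - site$state_charges[1, ]
}

#' Identify titratable sites in a structure
#'
#' Scans for Asp/Glu/Arg/Lys/Cys/Tyr/His residues (plus user-flagged
#' redox-active Trp) and instantiates sites with the bundled state charges and
#' reference values.  Ligand or otherwise constrained residues can be clamped
#' via \code{fixed_states}.
#'
#' @param structure a \code{pb_structure}
#' @param redox_trp character vector of "chain:resno" Trp residues to treat as
#'   redox sites (Trp/Trp+., reference Em 1070 mV)
#' @param fixed_states named character vector: names are "chain:resno",
#'   values are state labels to clamp (e.g. a ligand His held neutral)
#' @return list of \code{titratable_site}
#' @export
define_sites <- function(structure, redox_trp = character(),
                         fixed_states = character()) {
  a <- structure$atoms
  st <- titration_states_table()
  refs <- reference_values()
  res_key <- paste(a$chain_id, a$residue_number, sep = ":")
  sites <- list()
  for (rk in unique(res_key)) {
    rows <- which(res_key == rk)
    resname <- a$residue_name[rows[1]]
    is_trp_redox <- resname == "TRP" && rk %in% redox_trp
    if (!resname %in% unique(st$residue) && !is_trp_redox) next
    if (resname == "TRP" && !is_trp_redox) next
    stt <- st[st$residue == resname, , drop = FALSE]
    if (nrow(stt) == 0)
      stop("no bundled charge states for residue ", resname)
    kind <- stt$kind[1]
    atoms_needed <- unique(stt$atom)
    midx <- rows[match(atoms_needed, a$atom_name[rows])]
    if (any(is.na(midx)))
      stop("site ", rk, " (", resname, "): missing atoms ",
           paste(atoms_needed[is.na(midx)], collapse = ", "))
    states <- unique(stt$state)
    m <- matrix(0, length(states), length(atoms_needed),
                dimnames = list(states, atoms_needed))
    for (i in seq_len(nrow(stt)))
      m[stt$state[i], stt$atom[i]] <- stt$charge[i]
    ref <- switch(kind,
                  acid = , base = unname(refs[[resname]]),
                  his_tautomer = refs$HIS,
                  redox = refs$TRP_Em_mV)
    fx <- if (rk %in% names(fixed_states)) unname(fixed_states[[rk]]) else NULL
    sites[[length(sites) + 1]] <- titratable_site(
      site_id = paste0(resname, "-", rk), kind = kind, member_atoms = midx,
      state_charges = m, reference = ref, fixed_state = fx)
  }
  sites
}

#' Tally ionized groups in membrane slabs along z
#'
#' Each ionized group is approximated as a unit charge at the centroid of its
#' charged atoms, then binned into layers of \code{layer_thickness} measured
#' inward from each interface plane (two layers per side by default, plus the
#' remaining core region), mirroring the standard layered-charge bookkeeping
#' for membrane proteins.
#'
#' @param structure a \code{pb_structure}
#' @param sites optional list of \code{titratable_site}; their equilibrium
#'   states supply the group charges
#' @param site_states named integer/character vector of equilibrium state per
#'   site (default: reference state)
#' @param layer_thickness layer width in Angstrom (default 5)
#' @param interfaces numeric(2): z of the two surfaces; defaults to the
#'   structure's declared \code{z_interfaces}
#' @param n_layers layers tallied inward from each surface (default 2)
#' @return data.frame: region, z_lo, z_hi, n_pos, n_neg, net
#' @export
region_charge_tally <- function(structure, sites = NULL, site_states = NULL,
                                layer_thickness = 5, interfaces = NULL,
                                n_layers = 2) {
  a <- structure$atoms
  if (is.null(interfaces)) interfaces <- structure$z_interfaces
  if (is.null(interfaces) || length(interfaces) != 2)
    stop("need two interface z-planes")
  interfaces <- sort(interfaces)
  zr <- range(a$z)
  if (interfaces[2] < zr[1] || interfaces[1] > zr[2])
    stop("interfaces lie outside the structure's coordinate range")
  groups <- ionized_groups(structure, sites, site_states)
  # layers inward from the lower surface, core, layers inward from upper
  lo <- interfaces[1]; hi <- interfaces[2]
  b_lo <- lo + layer_thickness * (0:n_layers)
  b_hi <- hi - layer_thickness * (n_layers:0)
  if (b_lo[n_layers + 1] > b_hi[1]) stop("layers overlap: membrane too thin")
  bounds <- rbind(cbind(b_lo[-(n_layers + 1)], b_lo[-1]),
                  c(b_lo[n_layers + 1], b_hi[1]),
                  cbind(b_hi[-(n_layers + 1)], b_hi[-1]))
  out <- data.frame(region = seq_len(nrow(bounds)),
                    z_lo = bounds[, 1], z_hi = bounds[, 2],
                    n_pos = 0L, n_neg = 0L, net = 0L)
  if (nrow(groups) > 0) {
    for (r in seq_len(nrow(bounds))) {
      inb <- groups$z >= bounds[r, 1] & groups$z < bounds[r, 2]
      out$n_pos[r] <- sum(groups$sign[inb] > 0)
      out$n_neg[r] <- sum(groups$sign[inb] < 0)
    }
    out$net <- out$n_pos - out$n_neg
  }
  out
}

# Unit-charge group list: (z of charged-group centroid, sign).  Titratable
# sites contribute at their given equilibrium state; non-site residues
# contribute when their summed charge rounds to a nonzero integer.
ionized_groups <- function(structure, sites = NULL, site_states = NULL) {
  a <- structure$atoms
  site_atoms <- integer(0)
  res <- list()
  if (!is.null(sites)) {
    for (s in sites) {
      st <- 1L
      if (!is.null(site_states) && s$site_id %in% names(site_states)) {
        st <- site_states[[s$site_id]]
        if (is.character(st)) st <- match(st, rownames(s$state_charges))
      } else if (!is.null(s$fixed_state)) {
        st <- match(s$fixed_state, rownames(s$state_charges))
      }
      q <- s$state_charges[st, ]
      net <- round(sum(q))
      site_atoms <- c(site_atoms, s$member_atoms)
      if (net != 0) {
        w <- abs(q); w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(q), length(q))
        res[[length(res) + 1]] <- data.frame(
          z = sum(a$z[s$member_atoms] * w), sign = sign(net))
      }
    }
  }
  rest <- setdiff(seq_len(nrow(a)), site_atoms)
  if (length(rest) > 0) {
    key <- paste(a$chain_id[rest], a$residue_number[rest], sep = ":")
    for (rk in unique(key)) {
      rows <- rest[key == rk]
      net <- round(sum(a$charge[rows]))
      if (net != 0) {
        w <- abs(a$charge[rows])
        w <- if (sum(w) > 0) w / sum(w) else rep(1 / length(rows), length(rows))
        res[[length(res) + 1]] <- data.frame(
          z = sum(a$z[rows] * w), sign = sign(net))
      }
    }
  }
  if (length(res) == 0)
    return(data.frame(z = numeric(0), sign = numeric(0)))
  do.call(rbind, res)
}

#' Edge-to-edge distance between two residues
#'
#' The minimum distance between non-hydrogen side-chain atoms of the two
#' residues — the convention used with the Moser-Dutton ruler.
#'
#' @param structure a \code{pb_structure}
#' @param resA,resB residue identifiers "chain:resno"
#' @return distance in Angstrom
#' @export
edge_to_edge_distance <- function(structure, resA, resB) {
  a <- structure$atoms
  pick <- function(id) {
    parts <- strsplit(id, ":")[[1]]
    rows <- which(a$chain_id == parts[1] & a$residue_number == as.integer(parts[2]))
    if (length(rows) == 0) stop("residue not found: ", id)
    side <- rows[!a$atom_name[rows] %in% c("N", "CA", "C", "O", "OXT") &
                 !grepl("^[0-9]*H", a$atom_name[rows])]
    if (length(side) == 0) stop("residue ", id, " has no side-chain atoms")
    side
  }
  ia <- pick(resA); ib <- pick(resB)
  xa <- atom_coords(structure)[ia, , drop = FALSE]
  xb <- atom_coords(structure)[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * xa %*% t(xb)
  sqrt(max(min(d2), 0))
}
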