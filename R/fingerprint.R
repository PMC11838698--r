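# Circular (Morgan/ECFP-style) fingerprints over a SMILES-subset molecular
# graph parser.
#
# The parser covers the organic subset (B C N O P S F Cl Br I), aromatic
# lowercase atoms, bracket atoms with isotope / explicit H / charge, branches,
# ring-bond closures (digits and %nn), and '.' fragment separators. Stereo
# markers (/ \ @) are accepted and ignored. Bit positions follow this
# package's own order-independent hashing, not RDKit's: fingerprints are
# deterministic and invariant to atom input order, but not bit-compatible
# with other toolkits.

ELEMENT_Z <- c(
  H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, P = 15, S = 16,
  Cl = 17, Br = 35, I = 53, Se = 34, Si = 14
)

DEFAULT_VALENCE <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, P = 3, S = 2, Cl = 1, Br = 1, I = 1,
  Se = 2, Si = 4
)

#' Parse a SMILES string into a molecular graph
#'
#' Internal parser supporting the organic subset plus bracket atoms. Returns
#' atoms (element, aromatic flag, charge, explicit H count) and bonds
#' (endpoints and order; aromatic bonds carry order 1.5).
#'
#' @param smiles a single SMILES string
#' @return a list with `atoms` (data.frame) and `bonds` (data.frame)
#' @noRd
parse_smiles <- function(smiles) {
  if (!is.character(smiles) || length(smiles) != 1L || is.na(smiles) || !nzchar(smiles))
    stop_dti("SMILES must be a single non-empty string", "dti_parse_error")
  bad <- function(why) stop_dti(
    sprintf("cannot parse SMILES '%s': %s", smiles, why), "dti_parse_error")

  chars <- strsplit(smiles, "")[[1]]
  n <- length(chars)
  atoms <- list()
  bonds <- list()
  prev <- NA_integer_          # previous atom index
  stack <- integer(0)          # branch stack
  pending_bond <- NA_real_     # explicit bond order before next atom
  rings <- list()              # ring-closure label -> c(atom, order)

  add_atom <- function(elem, aromatic, charge = 0L, hcount = NA_integer_) {
    atoms[[length(atoms) + 1L]] <<- list(
      elem = elem, aromatic = aromatic, charge = charge, hcount = hcount)
    length(atoms)
  }
  add_bond <- function(i, j, order) {
    if (i == j) bad("ring bond to self")
    bonds[[length(bonds) + 1L]] <<- list(i = i, j = j, order = order)
  }
  connect <- function(idx) {
    if (!is.na(prev)) {
      ord <- pending_bond
      if (is.na(ord)) {
        a <- atoms[[prev]]; b <- atoms[[idx]]
        ord <- if (a$aromatic && b$aromatic) 1.5 else 1
      }
      add_bond(prev, idx, ord)
    }
    prev <<- idx
    pending_bond <<- NA_real_
  }

  i <- 1L
  while (i <= n) {
    ch <- chars[i]
    if (ch == "[") {
      j <- i + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) bad("unclosed bracket atom")
      body <- paste(chars[(i + 1L):(j - 1L)], collapse = "")
      m <- regmatches(body, regexec(
        "^([0-9]*)([A-Z][a-z]?|[bcnops]|se)(@{0,2})(H([0-9]*))?([+-]+[0-9]*)?$", body))[[1]]
      if (length(m) == 0) bad(sprintf("bad bracket atom [%s]", body))
      sym <- m[3]
      aromatic <- sym %in% c("b", "c", "n", "o", "p", "s", "se")
      elem <- if (aromatic) {
        paste0(toupper(substr(sym, 1, 1)), substring(sym, 2))
      } else sym
      if (!elem %in% names(ELEMENT_Z)) bad(sprintf("unknown element '%s'", elem))
      hcount <- if (nzchar(m[5])) {
        if (nzchar(m[6])) as.integer(m[6]) else 1L
      } else 0L
      chg <- 0L
      if (!is.na(m[7]) && nzchar(m[7])) {
        sign <- if (substr(m[7], 1, 1) == "+") 1L else -1L
        digits <- gsub("[+-]", "", m[7])
        chg <- if (nzchar(digits)) sign * as.integer(digits)
               else sign * nchar(gsub("[0-9]", "", m[7]))
      }
      idx <- add_atom(elem, aromatic, chg, hcount)
      connect(idx)
      i <- j + 1L
    } else if (ch %in% c("C", "B", "N", "O", "P", "S", "F", "I")) {
      two <- if (i < n) paste0(ch, chars[i + 1L]) else ""
      if (two %in% c("Cl", "Br")) {
        idx <- add_atom(two, FALSE)
        i <- i + 2L
      } else {
        idx <- add_atom(ch, FALSE)
        i <- i + 1L
      }
      connect(idx)
    } else if (ch %in% c("b", "c", "n", "o", "p", "s")) {
      idx <- add_atom(toupper(ch), TRUE)
      connect(idx)
      i <- i + 1L
    } else if (ch %in% c("-", "/", "\\")) {
      pending_bond <- 1; i <- i + 1L
    } else if (ch == "=") {
      pending_bond <- 2; i <- i + 1L
    } else if (ch == "#") {
      pending_bond <- 3; i <- i + 1L
    } else if (ch == ":") {
      pending_bond <- 1.5; i <- i + 1L
    } else if (ch == "(") {
      if (is.na(prev)) bad("branch before any atom")
      stack <- c(stack, prev); i <- i + 1L
    } else if (ch == ")") {
      if (length(stack) == 0) bad("unbalanced ')'")
      prev <- stack[length(stack)]
      stack <- stack[-length(stack)]
      i <- i + 1L
    } else if (ch == ".") {
      prev <- NA_integer_; pending_bond <- NA_real_; i <- i + 1L
    } else if (grepl("[0-9]", ch) || ch == "%") {
      if (is.na(prev)) bad("ring closure before any atom")
      if (ch == "%") {
        if (i + 2L > n) bad("truncated %nn ring label")
        lab <- paste(chars[(i + 1L):(i + 2L)], collapse = "")
        if (!grepl("^[0-9]{2}$", lab)) bad("bad %nn ring label")
        i <- i + 3L
      } else {
        lab <- ch; i <- i + 1L
      }
      if (is.null(rings[[lab]])) {
        rings[[lab]] <- c(prev, pending_bond)
        pending_bond <- NA_real_
      } else {
        opened <- rings[[lab]]
        ord <- pending_bond
        if (is.na(ord)) ord <- opened[2]
        if (is.na(ord)) {
          a <- atoms[[opened[1]]]; b <- atoms[[prev]]
          ord <- if (a$aromatic && b$aromatic) 1.5 else 1
        }
        add_bond(opened[1], prev, ord)
        rings[[lab]] <- NULL
        pending_bond <- NA_real_
      }
    } else if (ch == "@") {
      i <- i + 1L  # chirality ignored
    } else {
      bad(sprintf("unexpected character '%s' at position %d", ch, i))
    }
  }
  if (length(stack) > 0) bad("unbalanced '('")
  if (length(rings) > 0) bad("unclosed ring bond")
  if (length(atoms) == 0) bad("no atoms")

  atoms_df <- data.frame(
    elem = vapply(atoms, `[[`, "", "elem"),
    aromatic = vapply(atoms, `[[`, FALSE, "aromatic"),
    charge = vapply(atoms, function(a) as.integer(a$charge), 0L),
    hcount = vapply(atoms, function(a) as.integer(a$hcount), NA_integer_),
    stringsAsFactors = FALSE
  )
  bonds_df <- if (length(bonds)) data.frame(
    i = as.integer(vapply(bonds, `[[`, 0, "i")),
    j = as.integer(vapply(bonds, `[[`, 0, "j")),
    order = vapply(bonds, `[[`, 0, "order")
  ) else data.frame(i = integer(0), j = integer(0), order = numeric(0))

  # implicit hydrogens from default valence (bracket atoms keep explicit H)
  deg_order <- numeric(nrow(atoms_df))
  if (nrow(bonds_df)) for (b in seq_len(nrow(bonds_df))) {
    deg_order[bonds_df$i[b]] <- deg_order[bonds_df$i[b]] + bonds_df$order[b]
    deg_order[bonds_df$j[b]] <- deg_order[bonds_df$j[b]] + bonds_df$order[b]
  }
  impl <- is.na(atoms_df$hcount)
  val <- DEFAULT_VALENCE[atoms_df$elem]
  atoms_df$hcount[impl] <- pmax(0L, as.integer(val[impl] - ceiling(deg_order[impl])))
  list(atoms = atoms_df, bonds = bonds_df, smiles = smiles)
}

#' Morgan (circular) fingerprint of a molecule
#'
#' Computes an ECFP-style hashed circular fingerprint: atom invariants
#' (element, heavy degree, H count, charge, aromaticity) are iteratively
#' refined over `radius` rounds by hashing the sorted multiset of
#' (bond order, neighbour identifier) pairs, and every identifier seen at any
#' radius sets one bit modulo `n_bits`. The construction is invariant to the
#' order atoms appear in the SMILES, so different writings of the same
#' molecule (e.g. "OCC" and "CCO") give identical fingerprints.
#'
#' @param smiles a single SMILES string (organic subset; see Details)
#' @param n_bits fingerprint length in bits (default 2048)
#' @param radius maximum circular-environment radius (default 2)
#' @return an integer vector of 0/1 of length `n_bits`
#' @examples
#' fp <- morgan_fingerprint("CCO")
#' sum(fp) > 0
#' identical(morgan_fingerprint("OCC"), morgan_fingerprint("CCO"))
#' @export
morgan_fingerprint <- function(smiles, n_bits = 2048L, radius = 2L) {
  if (!is_scalar_number(n_bits) || n_bits <= 0 || n_bits != round(n_bits))
    stop_dti("n_bits must be a positive integer", "dti_config_error")
  if (!is_scalar_number(radius) || radius < 0 || radius != round(radius))
    stop_dti("radius must be a non-negative integer", "dti_config_error")
  mol <- parse_smiles(smiles)
  na <- nrow(mol$atoms)

  nbr <- vector("list", na)
  if (nrow(mol$bonds)) for (b in seq_len(nrow(mol$bonds))) {
    i <- mol$bonds$i[b]; j <- mol$bonds$j[b]; o <- mol$bonds$order[b]
    nbr[[i]] <- rbind(nbr[[i]], c(j, o))
    nbr[[j]] <- rbind(nbr[[j]], c(i, o))
  }
  deg <- vapply(nbr, function(x) if (is.null(x)) 0L else nrow(x), 0L)

  ids <- vapply(seq_len(na), function(a) {
    at <- mol$atoms[a, ]
    poly_hash(c(ELEMENT_Z[[at$elem]], deg[a], at$hcount, at$charge + 8L,
                as.integer(at$aromatic)))
  }, 0)

  codes <- ids
  if (radius > 0) for (r in seq_len(radius)) {
    new_ids <- vapply(seq_len(na), function(a) {
      if (deg[a] == 0L) return(poly_hash(c(r, ids[a])))
      pairs <- cbind(round(2 * nbr[[a]][, 2]), ids[nbr[[a]][, 1]])
      pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
      poly_hash(c(r, ids[a], as.vector(t(pairs))))
    }, 0)
    ids <- new_ids
    codes <- c(codes, ids)
  }

  fp <- integer(n_bits)
  fp[unique(codes %% n_bits) + 1L] <- 1L
  fp
}
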