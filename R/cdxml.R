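# ChemDraw CDXML structure export.
#
# Every residue carries an all-atom side-chain template (heavy atoms only;
# hydrogens stay implicit and are reconciled from standard valences).
# Templates are chained on an amide backbone -- side chains sit on the
# alpha-carbon for peptides and on the backbone nitrogen for peptoids (the
# N-substituted glycine connectivity) -- and terminus templates cap the ends.
# Layout is functional, not aesthetic: a zig-zag backbone with side chains
# grown perpendicular, and deterministic ids so output is diff-stable.

# side-chain template: atoms (elements), bonds (list of c(i, j, order) in
# local indices), attach = atom bonded to the backbone attachment point,
# n_link = atom additionally bonded to the backbone N (proline-type rings).
sc <- function(atoms, bonds = list(), attach = 1L, n_link = NA_integer_) {
  list(atoms = atoms, bonds = bonds, attach = attach, n_link = n_link)
}
lin <- function(...) {
  els <- c(...)
  bonds <- if (length(els) > 1) lapply(seq_len(length(els) - 1L),
                                       function(i) c(i, i + 1L, 1L)) else list()
  sc(els, bonds)
}
# mono-substituted benzene ring appended after `pre` chain atoms; ring
# attaches to the last chain atom
with_phenyl <- function(pre_atoms, pre_bonds, tail_idx) {
  r <- length(pre_atoms)  # ring atoms r+1 .. r+6
  sc(c(pre_atoms, rep("C", 6)),
     c(pre_bonds, list(
       c(tail_idx, r + 1L, 1L),
       c(r + 1L, r + 2L, 2L), c(r + 2L, r + 3L, 1L), c(r + 3L, r + 4L, 2L),
       c(r + 4L, r + 5L, 1L), c(r + 5L, r + 6L, 2L), c(r + 6L, r + 1L, 1L))))
}

side_chain_templates <- function() {
  phenol <- local({  # CB + para-hydroxyphenyl (tyrosine)
    t <- with_phenyl("C", list(), 1L)
    t$atoms <- c(t$atoms, "O")
    t$bonds <- c(t$bonds, list(c(5L, 8L, 1L)))
    t
  })
  phospho_tail <- function(t, o_idx) {  # -O-PO(OH)2 grafted onto atom o_idx
    p <- length(t$atoms)
    t$atoms <- c(t$atoms, "P", "O", "O", "O")
    t$bonds <- c(t$bonds, list(c(o_idx, p + 1L, 1L), c(p + 1L, p + 2L, 2L),
                               c(p + 1L, p + 3L, 1L), c(p + 1L, p + 4L, 1L)))
    t
  }
  peptide <- list(
    G = NULL,
    A = lin("C"),
    V = sc(c("C", "C", "C"), list(c(1L, 2L, 1L), c(1L, 3L, 1L))),
    L = sc(c("C", "C", "C", "C"),
           list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(2L, 4L, 1L))),
    I = sc(c("C", "C", "C", "C"),
           list(c(1L, 2L, 1L), c(1L, 3L, 1L), c(3L, 4L, 1L))),
    P = sc(c("C", "C", "C"), list(c(1L, 2L, 1L), c(2L, 3L, 1L)),
           n_link = 3L),
    F = with_phenyl("C", list(), 1L),
    Y = phenol,
    W = sc(c("C", "C", "C", "N", "C", "C", "C", "C", "C", "C"),
           list(c(1L, 2L, 1L), c(2L, 3L, 2L), c(3L, 4L, 1L), c(4L, 5L, 1L),
                c(5L, 6L, 1L), c(6L, 2L, 1L), c(5L, 10L, 2L), c(10L, 9L, 1L),
                c(9L, 8L, 2L), c(8L, 7L, 1L), c(7L, 6L, 2L))),
    S = lin("C", "O"),
    T = sc(c("C", "O", "C"), list(c(1L, 2L, 1L), c(1L, 3L, 1L))),
    C = lin("C", "S"),
    M = lin("C", "C", "S", "C"),
    N = sc(c("C", "C", "O", "N"),
           list(c(1L, 2L, 1L), c(2L, 3L, 2L), c(2L, 4L, 1L))),
    Q = sc(c("C", "C", "C", "O", "N"),
           list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 2L), c(3L, 5L, 1L))),
    D = sc(c("C", "C", "O", "O"),
           list(c(1L, 2L, 1L), c(2L, 3L, 2L), c(2L, 4L, 1L))),
    E = sc(c("C", "C", "C", "O", "O"),
           list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 2L), c(3L, 5L, 1L))),
    K = lin("C", "C", "C", "C", "N"),
    R = sc(c("C", "C", "C", "N", "C", "N", "N"),
           list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 5L, 1L),
                c(5L, 6L, 2L), c(5L, 7L, 1L))),
    H = sc(c("C", "C", "N", "C", "N", "C"),
           list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 5L, 2L),
                c(5L, 6L, 1L), c(6L, 2L, 2L))),
    pS = phospho_tail(lin("C", "O"), 2L),
    pT = local({
      t <- sc(c("C", "O", "C"), list(c(1L, 2L, 1L), c(1L, 3L, 1L)))
      phospho_tail(t, 2L)
    }),
    pY = phospho_tail(phenol, 8L),
    Nle = lin("C", "C", "C", "C"),
    Orn = lin("C", "C", "C", "N"),
    Cit = sc(c("C", "C", "C", "N", "C", "O", "N"),
             list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 5L, 1L),
                  c(5L, 6L, 2L), c(5L, 7L, 1L)))
  )
  peptoid <- list(
    Nme = lin("C"),
    Net = lin("C", "C"),
    Npr = lin("C", "C", "C"),
    Nbu = lin("C", "C", "C", "C"),
    Npm = with_phenyl("C", list(), 1L),
    Npe = with_phenyl(c("C", "C"), list(c(1L, 2L, 1L)), 2L),
    Nspe = with_phenyl(c("C", "C"), list(c(1L, 2L, 1L)), 1L),
    Nae = lin("C", "C", "N"),
    Nab = lin("C", "C", "C", "C", "N"),
    Nce = sc(c("C", "C", "C", "O", "O"),
             list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 2L), c(3L, 5L, 1L))),
    Nhe = lin("C", "C", "O")
  )
  list(peptide = peptide, peptoid = peptoid)
}

# terminus templates keyed by "<end>:<name>"; attach atom 1 bonds to the
# terminal backbone N (N-terminus) or carbonyl C (C-terminus)
terminus_templates <- function() {
  list(
    "N:unmodified" = sc(character(0)),
    "N:acetyl" = sc(c("C", "O", "C"), list(c(1L, 2L, 2L), c(1L, 3L, 1L))),
    "N:formyl" = sc(c("C", "O"), list(c(1L, 2L, 2L))),
    "C:acid" = sc("O"),
    "C:amide" = sc("N"),
    "C:methyl ester" = lin("O", "C"),
    "C:ethyl 3-mercaptopropionate thioester" =
      sc(c("S", "C", "C", "C", "O", "O", "C", "C"),
         list(c(1L, 2L, 1L), c(2L, 3L, 1L), c(3L, 4L, 1L), c(4L, 5L, 2L),
              c(4L, 6L, 1L), c(6L, 7L, 1L), c(7L, 8L, 1L)))
  )
}

STANDARD_VALENCE <- c(C = 4L, N = 3L, O = 2L, S = 2L, P = 5L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)
ATOMIC_NUMBER <- c(H = 1L, C = 6L, N = 7L, O = 8L, F = 9L, Na = 11L, P = 15L,
                   S = 16L, Cl = 17L, K = 19L, Br = 35L, I = 53L)

#' Build an all-atom structure graph for a sequence
#'
#' Chains the residue templates on an amide backbone (tertiary amide for
#' peptoids, whose side chains sit on the backbone nitrogen), caps both
#' termini, lays the backbone out on a zig-zag and grows side chains
#' perpendicular to it.  Hydrogens are implicit; the heavy-atom element
#' counts plus implicit hydrogens reproduce [molecular_formula()].
#'
#' @param seq a `polymer_seq` whose residues and termini all have structure
#'   templates (custom-formula termini do not).
#' @return A `structure_graph`: list with data frames `atoms` (element, x, y,
#'   implicit_h) and `bonds` (a1, a2, order).
#' @export
build_structure <- function(seq) {
  stopifnot(inherits(seq, "polymer_seq"))
  templates <- side_chain_templates()[[seq$polymer_class]]
  for (code in unique(seq$codes)) {
    if (!code %in% names(templates)) {
      stop(sprintf("structure unavailable: residue '%s' has no structure template",
                   code), call. = FALSE)
    }
  }
  term_tpl <- terminus_templates()
  for (t in list(seq$n_term, seq$c_term)) {
    if (!paste(t$end, t$name, sep = ":") %in% names(term_tpl)) {
      stop(sprintf("structure unavailable: terminus '%s' has no structure template",
                   t$name), call. = FALSE)
    }
  }

  el <- character(0); xs <- numeric(0); ys <- numeric(0)
  bonds <- list()
  add_atom <- function(element, x, y) {
    el[length(el) + 1L] <<- element
    xs[length(xs) + 1L] <<- x
    ys[length(ys) + 1L] <<- y
    length(el)
  }
  add_bond <- function(a, b, order = 1L) {
    bonds[[length(bonds) + 1L]] <<- c(a, b, order)
  }
  add_template <- function(tpl, attach_to, x0, y0, dir) {
    if (length(tpl$atoms) == 0) return(integer(0))
    ids <- integer(length(tpl$atoms))
    for (k in seq_along(tpl$atoms)) {
      # deterministic perpendicular stack with a small x stagger per atom
      ids[k] <- add_atom(tpl$atoms[k],
                         x0 + 0.18 * ((k - 1L) %% 3L),
                         y0 + dir * 0.55 * k)
    }
    add_bond(attach_to, ids[tpl$attach], 1L)
    for (b in tpl$bonds) add_bond(ids[b[1]], ids[b[2]], b[3])
    ids
  }

  dx <- 0.62; zig <- 0.22
  n_res <- length(seq$codes)
  n_idx <- integer(n_res); c_idx <- integer(n_res)
  for (i in seq_len(n_res)) {
    bx <- (i - 1L) * 3L * dx
    yN <- if ((3L * (i - 1L)) %% 2L == 0L) zig else -zig
    yCA <- if ((3L * (i - 1L) + 1L) %% 2L == 0L) zig else -zig
    yC <- if ((3L * (i - 1L) + 2L) %% 2L == 0L) zig else -zig
    N <- add_atom("N", bx, yN)
    CA <- add_atom("C", bx + dx, yCA)
    C <- add_atom("C", bx + 2 * dx, yC)
    O <- add_atom("O", bx + 2 * dx, yC - 1.0)
    add_bond(N, CA); add_bond(CA, C); add_bond(C, O, 2L)
    if (i > 1L) add_bond(c_idx[i - 1L], N)  # backbone amide bond
    n_idx[i] <- N; c_idx[i] <- C
    tpl <- templates[[seq$codes[i]]]
    if (!is.null(tpl) && length(tpl$atoms) > 0) {
      dir <- if (i %% 2L == 0L) -1 else 1
      anchor <- if (seq$polymer_class == "peptoid") N else CA
      ax <- if (seq$polymer_class == "peptoid") bx else bx + dx
      ids <- add_template(tpl, anchor, ax, if (dir > 0) zig else -zig, dir)
      if (!is.na(tpl$n_link)) add_bond(ids[tpl$n_link], N, 1L)
    }
  }
  add_template(term_tpl[[paste("N", seq$n_term$name, sep = ":")]],
               n_idx[1], -dx, 0, 1)
  add_template(term_tpl[[paste("C", seq$c_term$name, sep = ":")]],
               c_idx[n_res], (n_res - 1L) * 3L * dx + 3L * dx, 0, 1)

  bond_df <- as.data.frame(do.call(rbind, bonds))
  names(bond_df) <- c("a1", "a2", "order")
  order_sum <- numeric(length(el))
  for (b in seq_len(nrow(bond_df))) {
    order_sum[bond_df$a1[b]] <- order_sum[bond_df$a1[b]] + bond_df$order[b]
    order_sum[bond_df$a2[b]] <- order_sum[bond_df$a2[b]] + bond_df$order[b]
  }
  val <- STANDARD_VALENCE[el]
  if (anyNA(val)) {
    stop("no standard valence for element(s): ",
         paste(unique(el[is.na(val)]), collapse = ", "), call. = FALSE)
  }
  implicit_h <- val - order_sum
  if (any(implicit_h < 0)) {
    stop("internal error: bond orders exceed standard valence", call. = FALSE)
  }
  structure(list(
    atoms = data.frame(element = el, x = xs, y = ys,
                       implicit_h = as.integer(implicit_h)),
    bonds = bond_df), class = "structure_graph")
}

#' @export
print.structure_graph <- function(x, ...) {
  cat(sprintf("<structure_graph> %d heavy atoms, %d bonds, formula %s\n",
              nrow(x$atoms), nrow(x$bonds), format(graph_formula(x))))
  invisible(x)
}

#' Molecular formula of a structure graph
#'
#' Heavy-atom element counts plus the summed implicit hydrogens; used to
#' verify that a built structure conserves the sequence's composition.
#'
#' @param graph a `structure_graph`.
#' @return A [chem_formula()].
#' @export
graph_formula <- function(graph) {
  stopifnot(inherits(graph, "structure_graph"))
  counts <- table(graph$atoms$element)
  lst <- as.list(stats::setNames(as.integer(counts), names(counts)))
  h <- sum(graph$atoms$implicit_h)
  if (h > 0) lst[["H"]] <- (if (is.null(lst[["H"]])) 0L else lst[["H"]]) + h
  do.call(chem_formula, lst)
}

#' Write a structure graph as CDXML
#'
#' Emits a minimal, well-formed ChemDraw CDXML document (document, page,
#' fragment, node and bond elements).  Ids follow traversal order and
#' coordinates are fixed-precision, so identical input gives byte-identical
#' output.
#'
#' @param graph a non-empty `structure_graph`.
#' @param path optional output file path.
#' @return The CDXML text, invisibly when `path` is given.
#' @export
write_cdxml <- function(graph, path = NULL) {
  stopifnot(inherits(graph, "structure_graph"))
  if (nrow(graph$atoms) == 0) {
    stop("refusing to write an empty structure", call. = FALSE)
  }
  doc <- xml2::xml_new_root("CDXML")
  xml2::xml_set_attrs(doc, c(BondLength = "30"))
  page <- xml2::xml_add_child(doc, "page")
  frag <- xml2::xml_add_child(page, "fragment", id = "1")
  next_id <- 2L
  atom_ids <- integer(nrow(graph$atoms))
  for (i in seq_len(nrow(graph$atoms))) {
    a <- graph$atoms[i, ]
    attrs <- c(id = as.character(next_id),
               p = sprintf("%.4f %.4f", a$x * 30, a$y * 30))
    if (a$element != "C") {
      z <- ATOMIC_NUMBER[[a$element]]
      if (is.null(z) || is.na(z)) {
        stop("no atomic number for element: ", a$element, call. = FALSE)
      }
      attrs <- c(attrs, Element = as.character(z))
    }
    attrs <- c(attrs, NumHydrogens = as.character(a$implicit_h))
    node <- xml2::xml_add_child(frag, "n")
    xml2::xml_set_attrs(node, attrs)
    atom_ids[i] <- next_id
    next_id <- next_id + 1L
  }
  for (i in seq_len(nrow(graph$bonds))) {
    b <- graph$bonds[i, ]
    bond <- xml2::xml_add_child(frag, "b")
    xml2::xml_set_attrs(bond, c(id = as.character(next_id),
                                B = as.character(atom_ids[b$a1]),
                                E = as.character(atom_ids[b$a2]),
                                Order = as.character(b$order)))
    next_id <- next_id + 1L
  }
  txt <- as.character(doc)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}
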