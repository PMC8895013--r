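#' Write a crystal structure to CIF
#'
#' Emits the core items consumed by \code{\link{read_cif_structure}}: cell
#' constants, symmetry operators as xyz strings, fractional coordinates with
#' occupancies and U(iso/equiv), anisotropic U^ij, and (when present)
#' Gram-Charlier tensors as loops of unique components. The component
#' ordering of the Gram-Charlier loops follows \code{\link{gram_charlier}}.
#'
#' @param structure A \code{\link{crystal_structure}}.
#' @param path Output file path.
#' @param data_name CIF data block name.
#' @return \code{path} invisibly.
#' @export
write_cif_structure <- function(structure, path, data_name = "gridhar") {
  cl <- structure$cell
  out <- c(sprintf("data_%s", data_name),
           sprintf("_cell_length_a    %.6f", cl$a),
           sprintf("_cell_length_b    %.6f", cl$b),
           sprintf("_cell_length_c    %.6f", cl$c),
           sprintf("_cell_angle_alpha %.5f", cl$alpha),
           sprintf("_cell_angle_beta  %.5f", cl$beta),
           sprintf("_cell_angle_gamma %.5f", cl$gamma),
           sprintf("_cell_volume      %.5f", cl$volume),
           sprintf("_diffrn_radiation_wavelength %.6f", structure$wavelength),
           "loop_",
           " _space_group_symop_operation_xyz")
  for (op in structure$symmetry)
    out <- c(out, sprintf(" '%s'", format_symop_xyz(op)))
  out <- c(out, "loop_",
           " _atom_site_label", " _atom_site_type_symbol",
           " _atom_site_fract_x", " _atom_site_fract_y", " _atom_site_fract_z",
           " _atom_site_occupancy", " _atom_site_U_iso_or_equiv",
           " _atom_site_adp_type")
  for (at in structure$atoms) {
    ueq <- if (is.null(at$uaniso)) at$uiso else u_equiv(at$uaniso, cl)
    out <- c(out, sprintf(" %s %s %.6f %.6f %.6f %.4f %.6f %s",
                          at$label, at$element,
                          at$frac_pos[1], at$frac_pos[2], at$frac_pos[3],
                          at$occupancy, ueq,
                          if (is.null(at$uaniso)) "Uiso" else "Uani"))
  }
  aniso <- Filter(function(a) !is.null(a$uaniso), structure$atoms)
  if (length(aniso) > 0) {
    out <- c(out, "loop_",
             " _atom_site_aniso_label",
             " _atom_site_aniso_U_11", " _atom_site_aniso_U_22",
             " _atom_site_aniso_U_33", " _atom_site_aniso_U_12",
             " _atom_site_aniso_U_13", " _atom_site_aniso_U_23")
    for (at in aniso)
      out <- c(out, sprintf(" %s %.6f %.6f %.6f %.6f %.6f %.6f", at$label,
                            at$uaniso[1], at$uaniso[2], at$uaniso[3],
                            at$uaniso[4], at$uaniso[5], at$uaniso[6]))
  }
  gc3a <- Filter(function(a) !is.null(a$gc3), structure$atoms)
  if (length(gc3a) > 0) {
    tab <- gc3_index_table()
    tags <- apply(tab$idx, 1, paste, collapse = "")
    out <- c(out, "loop_", " _atom_site_anharm_gc_c_label",
             sprintf(" _atom_site_anharm_gc_c_%s", tags))
    for (at in gc3a)
      out <- c(out, paste(" ", at$label,
                          paste(sprintf("%.8e", at$gc3), collapse = " ")))
  }
  gc4a <- Filter(function(a) !is.null(a$gc4), structure$atoms)
  if (length(gc4a) > 0) {
    tab <- gc4_index_table()
    tags <- apply(tab$idx, 1, paste, collapse = "")
    out <- c(out, "loop_", " _atom_site_anharm_gc_d_label",
             sprintf(" _atom_site_anharm_gc_d_%s", tags))
    for (at in gc4a)
      out <- c(out, paste(" ", at$label,
                          paste(sprintf("%.8e", at$gc4), collapse = " ")))
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a crystal structure from CIF
#'
#' Minimal CIF-subset reader for the items written by
#' \code{\link{write_cif_structure}}: cell constants, explicit symmetry
#' operator lists (no space-group symbol interpretation), atom sites,
#' anisotropic displacement parameters and Gram-Charlier loops. Values may
#' carry standard uncertainties in parentheses, which are stripped.
#'
#' @param path CIF file path.
#' @return A \code{\link{crystal_structure}}.
#' @export
read_cif_structure <- function(path) {
  toks <- cif_parse(path)
  num <- function(tag, default = NULL) {
    v <- toks$items[[tag]]
    if (is.null(v)) {
      if (is.null(default)) stop("CIF item missing: ", tag)
      return(default)
    }
    cif_numeric(v)
  }
  cell <- unit_cell(num("_cell_length_a"), num("_cell_length_b"),
                    num("_cell_length_c"),
                    num("_cell_angle_alpha", 90), num("_cell_angle_beta", 90),
                    num("_cell_angle_gamma", 90))
  wavelength <- num("_diffrn_radiation_wavelength", 0.71073)
  symmetry <- list(symop_identity())
  symtag <- intersect(c("_space_group_symop_operation_xyz",
                        "_symmetry_equiv_pos_as_xyz"),
                      unlist(lapply(toks$loops, function(l) l$tags)))
  if (length(symtag) > 0) {
    lp <- cif_find_loop(toks$loops, symtag[1])
    symmetry <- lapply(lp$rows[[symtag[1]]], parse_symop_xyz)
  }
  lp <- cif_find_loop(toks$loops, "_atom_site_label")
  if (is.null(lp)) stop("CIF has no atom_site loop")
  n <- length(lp$rows[["_atom_site_label"]])
  col <- function(tag, default = NA) {
    v <- lp$rows[[tag]]
    if (is.null(v)) rep(default, n) else v
  }
  labels <- col("_atom_site_label")
  elements <- col("_atom_site_type_symbol")
  if (all(is.na(elements))) elements <- gsub("[0-9].*$", "", labels)
  xs <- cif_numeric(col("_atom_site_fract_x"))
  ys <- cif_numeric(col("_atom_site_fract_y"))
  zs <- cif_numeric(col("_atom_site_fract_z"))
  occ <- cif_numeric(col("_atom_site_occupancy", "1"))
  uiso <- suppressWarnings(cif_numeric(col("_atom_site_U_iso_or_equiv", "0")))
  uiso[is.na(uiso)] <- 0
  aniso <- cif_find_loop(toks$loops, "_atom_site_aniso_label")
  gc3l <- cif_find_loop(toks$loops, "_atom_site_anharm_gc_c_label")
  gc4l <- cif_find_loop(toks$loops, "_atom_site_anharm_gc_d_label")
  atoms <- vector("list", n)
  for (i in seq_len(n)) {
    ua <- NULL
    if (!is.null(aniso)) {
      j <- match(labels[i], aniso$rows[["_atom_site_aniso_label"]])
      if (!is.na(j))
        ua <- cif_numeric(vapply(c("_atom_site_aniso_U_11", "_atom_site_aniso_U_22",
                                   "_atom_site_aniso_U_33", "_atom_site_aniso_U_12",
                                   "_atom_site_aniso_U_13", "_atom_site_aniso_U_23"),
                                 function(tg) aniso$rows[[tg]][j], character(1)))
    }
    g3 <- cif_gc_row(gc3l, labels[i], "_atom_site_anharm_gc_c_",
                     gc3_index_table())
    g4 <- cif_gc_row(gc4l, labels[i], "_atom_site_anharm_gc_d_",
                     gc4_index_table())
    atoms[[i]] <- atom(labels[i], elements[i], c(xs[i], ys[i], zs[i]),
                       occupancy = occ[i], uiso = uiso[i], uaniso = ua,
                       gc3 = g3, gc4 = g4)
  }
  crystal_structure(cell, symmetry, atoms, wavelength)
}

cif_gc_row <- function(loop, label, prefix, tab) {
  if (is.null(loop)) return(NULL)
  j <- match(label, loop$rows[[paste0(prefix, "label")]])
  if (is.na(j)) return(NULL)
  tags <- paste0(prefix, apply(tab$idx, 1, paste, collapse = ""))
  cif_numeric(vapply(tags, function(tg) loop$rows[[tg]][j], character(1)))
}

# strip standard uncertainties "1.234(5)" -> 1.234
cif_numeric <- function(v) as.numeric(gsub("\\(.*\\)", "", v))

cif_find_loop <- function(loops, tag) {
  for (l in loops) if (tag %in% l$tags) return(l)
  NULL
}

# minimal CIF tokenizer: key-value items plus loop_ blocks, quoted values,
# '#' comments; multi-line (semicolon) text fields are not supported
cif_parse <- function(path) {
  lines <- readLines(path, warn = FALSE)
  items <- list()
  loops <- list()
  i <- 1
  while (i <= length(lines)) {
    ln <- trimws(sub("#.*$", "", lines[i]))
    if (!nzchar(ln) || startsWith(ln, "data_")) { i <- i + 1; next }
    if (tolower(ln) == "loop_") {
      i <- i + 1
      tags <- character(0)
      while (i <= length(lines)) {
        tl <- trimws(sub("#.*$", "", lines[i]))
        if (startsWith(tl, "_")) { tags <- c(tags, strsplit(tl, "\\s+")[[1]][1]); i <- i + 1 }
        else break
      }
      vals <- character(0)
      while (i <= length(lines)) {
        vl <- trimws(sub("#.*$", "", lines[i]))
        if (!nzchar(vl)) { i <- i + 1; next }
        if (startsWith(vl, "_") || tolower(vl) == "loop_" ||
            startsWith(vl, "data_")) break
        vals <- c(vals, cif_tokenize(vl))
        i <- i + 1
      }
      if (length(tags) > 0 && length(vals) %% length(tags) == 0 && length(vals) > 0) {
        m <- matrix(vals, ncol = length(tags), byrow = TRUE)
        rows <- stats::setNames(lapply(seq_along(tags), function(j) m[, j]), tags)
        loops[[length(loops) + 1]] <- list(tags = tags, rows = rows)
      }
      next
    }
    if (startsWith(ln, "_")) {
      parts <- cif_tokenize(ln)
      if (length(parts) >= 2) items[[parts[1]]] <- parts[2]
      i <- i + 1
      next
    }
    i <- i + 1
  }
  list(items = items, loops = loops)
}

# split a CIF line into tokens, honouring single/double quotes
cif_tokenize <- function(ln) {
  toks <- character(0)
  rest <- trimws(ln)
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch %in% c("'", '"')) {
      close <- regexpr(paste0(ch, "(\\s|$)"), substring(rest, 2))
      if (close == -1) {
        toks <- c(toks, gsub(paste0("^", ch, "|", ch, "$"), "", rest))
        break
      }
      toks <- c(toks, substr(rest, 2, close))
      rest <- trimws(substring(rest, close + 2))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp == -1) { toks <- c(toks, rest); break }
      toks <- c(toks, substr(rest, 1, sp - 1))
      rest <- trimws(substring(rest, sp))
    }
  }
  toks
}
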