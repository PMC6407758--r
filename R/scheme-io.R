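# Plain-text scheme files. Line-oriented, UTF-8, '#' comments, versioned
# header. Three sections:
#   [species]    name = initial_concentration        (mol/l)
#   [constants]  name = value  |  name = barrier:<J/mol>@<K>
#   [equations]  d[A]/dt = -k1*A*B + k2*C + 2*k3*X^2   (or `= 0`)

.nk_scheme_header <- "# netkin scheme v1"
.nk_num_re <- "[+-]?(?:[0-9]+\\.?[0-9]*|\\.[0-9]+)(?:[eE][+-]?[0-9]+)?"

#' Write a kinetic scheme to the plain-text scheme format
#'
#' The format round-trips: [read_scheme()] of the output reconstructs the
#' scheme field-for-field (barrier-derived constants are re-evaluated from
#' their stored barrier and temperature).
#'
#' @param scheme A [kinetic_scheme()].
#' @param path Optional file path; when `NULL` the text is only returned.
#' @return The scheme text as a single character string (invisibly when
#'   `path` is given).
#' @export
write_scheme <- function(scheme, path = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  num <- function(v) sprintf("%.17g", v)
  lines <- .nk_scheme_header
  if (!is.null(scheme$name)) lines <- c(lines, paste0("name = ", scheme$name))
  lines <- c(lines, "", "[species]")
  for (nm in names(scheme$species)) {
    lines <- c(lines, sprintf("%s = %s", nm, num(scheme$species[[nm]])))
  }
  lines <- c(lines, "", "[constants]")
  for (k in scheme$constants) {
    lines <- c(lines, if (k$origin == "barrier") {
      sprintf("%s = barrier:%s@%s", k$name, num(k$barrier), num(k$temperature))
    } else {
      sprintf("%s = %s", k$name, num(k$value))
    })
  }
  lines <- c(lines, "", "[equations]")
  for (eq in scheme$equations) {
    lines <- c(lines, .nk_format_equation_io(eq))
  }
  text <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, sep = "")
    return(invisible(text))
  }
  text
}

.nk_format_equation_io <- function(eq) {
  if (!length(eq$terms)) return(sprintf("d[%s]/dt = 0", eq$species))
  parts <- vapply(seq_along(eq$terms), function(i) {
    term <- eq$terms[[i]]
    sgn <- if (term$sign < 0) "-" else if (i == 1L) "" else "+"
    coef <- if (term$coef != 1) paste0(sprintf("%.17g", term$coef), "*") else ""
    fac <- if (length(term$factors)) {
      paste0("*", paste0(names(term$factors),
                         ifelse(term$factors != 1,
                                paste0("^", sprintf("%.17g", term$factors)),
                                "")),
             collapse = "")
    } else ""
    paste0(sgn, coef, term$constant, fac)
  }, character(1))
  sprintf("d[%s]/dt = %s", eq$species, paste(parts, collapse = " "))
}

.nk_io_stop <- function(lineno, fmt, ...) {
  stop(sprintf(paste0("scheme file, line %d: ", fmt), lineno, ...),
       call. = FALSE)
}

#' Read a kinetic scheme from the plain-text scheme format
#'
#' @param x Path to a scheme file, or the scheme text itself (a character
#'   vector of lines or a single string with embedded newlines).
#' @return A validated [kinetic_scheme()].
#' @export
read_scheme <- function(x) {
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    lines <- readLines(x, encoding = "UTF-8")
  } else {
    lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  }
  name <- NULL
  section <- ""
  species <- numeric(0)
  constants <- list()
  raw_equations <- list() # list of (lineno, species, rhs)
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[.*\\]$", line)) {
      section <- sub("^\\[(.*)\\]$", "\\1", line)
      if (!section %in% c("species", "constants", "equations")) {
        .nk_io_stop(i, "unknown section '[%s]'", section)
      }
      next
    }
    if (section == "" && grepl("^name\\s*=", line)) {
      name <- trimws(sub("^name\\s*=", "", line))
      next
    }
    if (section == "species") {
      m <- regmatches(line, regexec(
        paste0("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(", .nk_num_re, ")$"), line))[[1]]
      if (!length(m)) .nk_io_stop(i, "expected 'name = number', got '%s'", line)
      if (m[2] %in% names(species)) .nk_io_stop(i, "duplicate species '%s'", m[2])
      species[[m[2]]] <- as.numeric(m[3])
    } else if (section == "constants") {
      mb <- regmatches(line, regexec(
        paste0("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*barrier:(", .nk_num_re,
               ")@(", .nk_num_re, ")$"), line))[[1]]
      if (length(mb)) {
        if (mb[2] %in% names(constants)) {
          .nk_io_stop(i, "duplicate rate constant '%s'", mb[2])
        }
        constants[[mb[2]]] <- rate_constant(mb[2],
                                            barrier = as.numeric(mb[3]),
                                            temperature = as.numeric(mb[4]))
        next
      }
      m <- regmatches(line, regexec(
        paste0("^([A-Za-z][A-Za-z0-9_]*)\\s*=\\s*(", .nk_num_re, ")$"), line))[[1]]
      if (!length(m)) {
        .nk_io_stop(i, "expected 'name = value' or 'name = barrier:<J/mol>@<K>', got '%s'",
                    line)
      }
      if (m[2] %in% names(constants)) {
        .nk_io_stop(i, "duplicate rate constant '%s'", m[2])
      }
      constants[[m[2]]] <- rate_constant(m[2], value = as.numeric(m[3]))
    } else if (section == "equations") {
      m <- regmatches(line, regexec(
        "^d\\[([A-Za-z][A-Za-z0-9_]*)\\]/dt\\s*=\\s*(.+)$", line))[[1]]
      if (!length(m)) {
        .nk_io_stop(i, "expected 'd[species]/dt = ...', got '%s'", line)
      }
      raw_equations[[length(raw_equations) + 1L]] <-
        list(lineno = i, species = m[2], rhs = m[3])
    } else {
      .nk_io_stop(i, "content outside any section: '%s'", line)
    }
  }
  equations <- lapply(raw_equations, function(re) {
    rate_equation(re$species,
                  .nk_parse_rhs(re$rhs, re$lineno, names(species),
                                names(constants)))
  })
  eq_species <- vapply(raw_equations, `[[`, character(1), "species")
  for (re in raw_equations) {
    if (!re$species %in% names(species)) {
      .nk_io_stop(re$lineno, "equation for unknown species '%s'", re$species)
    }
  }
  dup <- eq_species[duplicated(eq_species)]
  if (length(dup)) {
    .nk_io_stop(raw_equations[[which(duplicated(eq_species))[1]]]$lineno,
                "duplicate equation for species '%s'", dup[1])
  }
  kinetic_scheme(species, constants, equations, name = name)
}

# Parse the right-hand side of an equation line into rate terms.
.nk_parse_rhs <- function(rhs, lineno, species_names, constant_names) {
  rhs <- gsub("\\s+", "", rhs)
  if (rhs == "0") return(list())
  # split into signed addends at top level (the grammar has no parentheses)
  pieces <- regmatches(rhs, gregexpr("[+-]?[^+-]+", rhs))[[1]]
  if (!length(pieces) || paste(pieces, collapse = "") != rhs) {
    .nk_io_stop(lineno, "cannot parse equation right-hand side '%s'", rhs)
  }
  lapply(pieces, function(piece) {
    sign <- if (startsWith(piece, "-")) -1 else 1
    body <- sub("^[+-]", "", piece)
    toks <- strsplit(body, "*", fixed = TRUE)[[1]]
    if (!length(toks) || any(!nzchar(toks))) {
      .nk_io_stop(lineno, "malformed term '%s'", piece)
    }
    coef <- 1
    if (grepl(paste0("^", .nk_num_re, "$"), toks[1])) {
      coef <- as.numeric(toks[1])
      toks <- toks[-1]
      if (!length(toks)) {
        .nk_io_stop(lineno, "term '%s' has a coefficient but no rate constant",
                    piece)
      }
    }
    kname <- toks[1]
    if (!grepl(.nk_name_re, kname)) {
      .nk_io_stop(lineno, "invalid rate-constant token '%s'", kname)
    }
    if (!kname %in% constant_names) {
      if (kname %in% species_names) {
        .nk_io_stop(lineno,
                    "term '%s' must start with a rate constant, but '%s' is a species",
                    piece, kname)
      }
      .nk_io_stop(lineno, "unknown rate constant '%s'", kname)
    }
    factors <- numeric(0)
    for (tok in toks[-1]) {
      fm <- regmatches(tok, regexec(
        paste0("^([A-Za-z][A-Za-z0-9_]*)(?:\\^(", .nk_num_re, "))?$"), tok))[[1]]
      if (!length(fm)) .nk_io_stop(lineno, "malformed factor '%s'", tok)
      sp <- fm[2]
      if (!sp %in% species_names) {
        .nk_io_stop(lineno, "unknown species '%s'", sp)
      }
      expo <- if (nzchar(fm[3])) as.numeric(fm[3]) else 1
      if (sp %in% names(factors)) {
        factors[[sp]] <- factors[[sp]] + expo
      } else {
        factors[[sp]] <- expo
      }
    }
    rate_term(kname, factors, sign = sign, coef = coef)
  })
}
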