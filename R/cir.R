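# SPICE netlist export/parse (PSpice analogue-behavioural dialect).
# Element cards: C<name> <node> 0 <cap> IC=<v0>, behavioural current sources
# G<name> 0 <node> VALUE = { <expr> } (current injected INTO the node when
# the expression is positive), R<name> <node> 0 <value>; plus .OPTIONS,
# .TRAN <print step> <total time> UIC, .PRINT TRAN and .END.
# Numbers are printed with "%.17G" so parse(export(x)) is value-exact.

.nk_cir_num <- function(v) sprintf("%.17G", v)

.nk_cir_expr <- function(source) {
  w <- source$sign * source$coef * source$value
  parts <- .nk_cir_num(w)
  if (length(source$factors)) {
    vs <- vapply(seq_along(source$factors), function(i) {
      nd <- paste0("N_", toupper(names(source$factors)[i]))
      e <- source$factors[[i]]
      if (e == 1) sprintf("V(%s)", nd) else
        sprintf("PWR(V(%s),%s)", nd, .nk_cir_num(e))
    }, character(1))
    parts <- paste(c(parts, vs), collapse = "*")
  }
  parts
}

#' Export an NSM network as a SPICE netlist
#'
#' Emits a deterministic PSpice-dialect `.CIR` netlist: one capacitor card
#' (unit capacitance, `IC=` initial voltage) per species, one behavioural
#' current source per rate term, one continuity resistor per node, the
#' `.OPTIONS`/`.TRAN` simulation cards and a `.PRINT` of all node voltages.
#' Element order is species order, then term order, so output is
#' byte-identical across runs for equal inputs.
#'
#' @param x An `nsm_network` or a [kinetic_scheme()] (converted with
#'   [build_network()]).
#' @param options A [sim_options()] object supplying the transient-analysis
#'   cards.
#' @return Netlist text, a single character string.
#' @export
export_cir <- function(x, options) {
  if (inherits(x, "kinetic_scheme")) x <- build_network(x)
  stopifnot(inherits(x, "nsm_network"), inherits(options, "sim_options"))
  nm <- c(x$capacitors$name, vapply(x$sources, `[[`, character(1), "name"),
          x$resistors$name)
  if (anyDuplicated(nm)) {
    stop("netlist element names collide after mangling: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  lines <- c(
    sprintf("* netkin NSM netlist v1: %s", x$scheme_name %||% "kinetic scheme"),
    sprintf("* species: %s", paste(x$nodes$species, collapse = " "))
  )
  for (i in seq_len(nrow(x$capacitors))) {
    lines <- c(lines, sprintf("%s %s 0 %s IC=%s",
                              x$capacitors$name[i], x$capacitors$node[i],
                              .nk_cir_num(x$capacitors$capacitance[i]),
                              .nk_cir_num(x$capacitors$ic[i])))
  }
  for (s in x$sources) {
    lines <- c(lines, sprintf("%s 0 %s VALUE = { %s }",
                              s$name, s$node, .nk_cir_expr(s)))
  }
  for (i in seq_len(nrow(x$resistors))) {
    lines <- c(lines, sprintf("%s %s 0 %s",
                              x$resistors$name[i], x$resistors$node[i],
                              .nk_cir_num(x$resistors$resistance[i])))
  }
  lines <- c(
    lines,
    sprintf(".OPTIONS RELTOL=%s NUMDGT=%d", .nk_cir_num(options$reltol),
            options$numdgt),
    sprintf(".TRAN %s %s UIC", .nk_cir_num(options$print_step),
            .nk_cir_num(options$total_time)),
    sprintf(".PRINT TRAN %s",
            paste(sprintf("V(%s)", x$nodes$node), collapse = " ")),
    ".END"
  )
  paste0(paste(lines, collapse = "\n"), "\n")
}

.nk_cir_stop <- function(lineno, fmt, ...) {
  stop(sprintf(paste0("netlist, line %d: ", fmt), lineno, ...), call. = FALSE)
}

# Parse "<w>" or "<w>*V(N_X)*PWR(V(N_Y),2)" back into (w, factors-by-node).
.nk_parse_expr <- function(expr, lineno) {
  toks <- strsplit(gsub("\\s+", "", expr), "*", fixed = TRUE)[[1]]
  if (!length(toks)) .nk_cir_stop(lineno, "empty VALUE expression")
  w <- suppressWarnings(as.numeric(toks[1]))
  if (is.na(w)) {
    .nk_cir_stop(lineno, "VALUE expression must start with a numeric coefficient, got '%s'",
                 toks[1])
  }
  factors <- numeric(0)
  for (tok in toks[-1]) {
    m <- regmatches(tok, regexec("^V\\(([A-Za-z0-9_]+)\\)$", tok))[[1]]
    if (length(m)) {
      nd <- m[2]; e <- 1
    } else {
      m <- regmatches(tok, regexec(
        paste0("^PWR\\(V\\(([A-Za-z0-9_]+)\\),(", .nk_num_re, ")\\)$"), tok))[[1]]
      if (!length(m)) .nk_cir_stop(lineno, "cannot parse VALUE factor '%s'", tok)
      nd <- m[2]; e <- as.numeric(m[3])
    }
    if (nd %in% names(factors)) {
      factors[[nd]] <- factors[[nd]] + e
    } else {
      factors[[nd]] <- e
    }
  }
  list(w = w, factors = factors)
}

#' Parse a SPICE netlist produced by [export_cir()]
#'
#' Inverse of [export_cir()] up to element naming: reconstructs the network
#' topology (nodes, capacitors with initial conditions, behavioural current
#' sources, resistors) and, when `.OPTIONS`/`.TRAN` cards are present, the
#' simulation options. Only the element dialect emitted by [export_cir()] is
#' accepted; any other card is rejected with its line number.
#'
#' @param text Netlist text (single string or character vector of lines).
#' @return An `nsm_network`; its `options` field holds a [sim_options()]
#'   when the netlist carried `.TRAN`.
#' @export
parse_cir <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE))
  species_line <- NULL
  caps <- list(); srcs <- list(); ress <- list()
  reltol <- NULL; numdgt <- NULL; tran <- NULL
  seen_end <- FALSE
  for (i in seq_along(lines)) {
    line <- trimws(lines[i])
    if (!nzchar(line)) next
    if (startsWith(line, "*")) {
      m <- regmatches(line, regexec("^\\*\\s*species:\\s*(.+)$", line))[[1]]
      if (length(m)) species_line <- strsplit(trimws(m[2]), "\\s+")[[1]]
      next
    }
    if (seen_end) .nk_cir_stop(i, "content after .END")
    first <- toupper(substr(line, 1, 1))
    if (first == ".") {
      if (grepl("^\\.OPTIONS\\b", line, ignore.case = TRUE)) {
        mr <- regmatches(line, regexec(paste0("RELTOL=(", .nk_num_re, ")"), line))[[1]]
        if (length(mr)) reltol <- as.numeric(mr[2])
        md <- regmatches(line, regexec("NUMDGT=([0-9]+)", line))[[1]]
        if (length(md)) numdgt <- as.integer(md[2])
      } else if (grepl("^\\.TRAN\\b", line, ignore.case = TRUE)) {
        mt <- regmatches(line, regexec(
          paste0("^\\.TRAN\\s+(", .nk_num_re, ")\\s+(", .nk_num_re, ")"),
          line))[[1]]
        if (!length(mt)) .nk_cir_stop(i, "cannot parse .TRAN card '%s'", line)
        tran <- c(print_step = as.numeric(mt[2]), total_time = as.numeric(mt[3]))
      } else if (grepl("^\\.PRINT\\b", line, ignore.case = TRUE)) {
        # output card; no model content
      } else if (grepl("^\\.END\\s*$", line, ignore.case = TRUE)) {
        seen_end <- TRUE
      } else {
        .nk_cir_stop(i, "unsupported control card '%s'", line)
      }
      next
    }
    if (first == "C") {
      m <- regmatches(line, regexec(paste0(
        "^(\\S+)\\s+(\\S+)\\s+0\\s+(", .nk_num_re, ")\\s+IC=(", .nk_num_re,
        ")\\s*$"), line))[[1]]
      if (!length(m)) .nk_cir_stop(i, "cannot parse capacitor card '%s'", line)
      caps[[length(caps) + 1L]] <- list(name = m[2], node = m[3],
                                        capacitance = as.numeric(m[4]),
                                        ic = as.numeric(m[5]))
    } else if (first == "G") {
      m <- regmatches(line, regexec(
        "^(\\S+)\\s+0\\s+(\\S+)\\s+VALUE\\s*=\\s*\\{(.*)\\}\\s*$", line))[[1]]
      if (!length(m)) .nk_cir_stop(i, "cannot parse current-source card '%s'", line)
      ex <- .nk_parse_expr(m[4], i)
      srcs[[length(srcs) + 1L]] <- list(name = m[2], node = m[3],
                                        w = ex$w, factors = ex$factors)
    } else if (first == "R") {
      m <- regmatches(line, regexec(paste0(
        "^(\\S+)\\s+(\\S+)\\s+0\\s+(", .nk_num_re, ")\\s*$"), line))[[1]]
      if (!length(m)) .nk_cir_stop(i, "cannot parse resistor card '%s'", line)
      ress[[length(ress) + 1L]] <- list(name = m[2], node = m[3],
                                        resistance = as.numeric(m[4]))
    } else {
      .nk_cir_stop(i, "unsupported element card '%s' (only C, G and R elements are part of the NSM dialect)",
                   line)
    }
  }
  if (!length(caps)) {
    stop("netlist contains no capacitor cards: not an NSM netlist",
         call. = FALSE)
  }
  node_names <- vapply(caps, `[[`, character(1), "node")
  if (!is.null(species_line) && length(species_line) == length(caps)) {
    species <- species_line
  } else {
    species <- sub("^N_", "", node_names)
  }
  node2sp <- setNames(species, node_names)
  nodes <- data.frame(species = species, node = node_names,
                      stringsAsFactors = FALSE)
  capacitors <- data.frame(
    name = vapply(caps, `[[`, character(1), "name"), node = node_names,
    capacitance = vapply(caps, `[[`, numeric(1), "capacitance"),
    ic = vapply(caps, `[[`, numeric(1), "ic"), stringsAsFactors = FALSE
  )
  sources <- lapply(seq_along(srcs), function(j) {
    s <- srcs[[j]]
    if (!s$node %in% node_names) {
      stop(sprintf("netlist: current source '%s' drives unknown node '%s'",
                   s$name, s$node), call. = FALSE)
    }
    fac <- s$factors
    if (length(fac)) {
      bad <- setdiff(names(fac), node_names)
      if (length(bad)) {
        stop(sprintf("netlist: current source '%s' senses unknown node '%s'",
                     s$name, bad[1]), call. = FALSE)
      }
      fac <- setNames(as.numeric(fac), unname(node2sp[names(fac)]))
      fac <- fac[order(names(fac))]
    } else {
      fac <- setNames(numeric(0), character(0))
    }
    list(name = s$name, node = s$node, species = unname(node2sp[[s$node]]),
         sign = if (s$w < 0) -1 else 1, coef = 1, constant = sprintf("g%d", j),
         value = abs(s$w), factors = fac)
  })
  if (length(ress) != length(caps)) {
    stop("netlist: resistor count does not match node count", call. = FALSE)
  }
  resistors <- data.frame(
    name = vapply(ress, `[[`, character(1), "name"),
    node = vapply(ress, `[[`, character(1), "node"),
    resistance = vapply(ress, `[[`, numeric(1), "resistance"),
    stringsAsFactors = FALSE
  )
  options <- NULL
  if (!is.null(tran)) {
    options <- sim_options(total_time = tran[["total_time"]],
                           print_step = tran[["print_step"]],
                           reltol = reltol %||% 1e-3,
                           numdgt = numdgt %||% 6L)
  }
  structure(
    list(nodes = nodes, capacitors = capacitors, sources = sources,
         resistors = resistors, scheme_name = NULL, options = options),
    class = "nsm_network"
  )
}
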