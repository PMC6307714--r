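# Versioned plain-text parameter and rotamer-library files.  All numbers are
# written with 17 significant digits, which round-trips IEEE doubles exactly.

fmt_num <- function(x) sprintf("%.17g", x)

parse_nums <- function(tokens, n, what, block) {
  v <- suppressWarnings(as.numeric(tokens))
  if (length(v) != n || anyNA(v))
    cg_error("cg_schema_error",
             sprintf("expected %d numeric values for %s, got %d",
                     n, what, length(tokens)), block = block)
  v
}

#' Write a parameter set to a text file
#'
#' Serializes every trainable block (and the layout configuration) of a
#' `cg_params` to a versioned, human-readable text file.  Values are written
#' with 17 significant digits so [read_params()] reproduces the set
#' bit-exactly.  The write is atomic (temp file + rename).
#'
#' @param pset a `cg_params`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_params <- function(pset, path) {
  stopifnot(inherits(pset, "cg_params"))
  cfg <- pset$config
  lines <- c(
    sprintf("cgfold-params v%d", pset$version),
    sprintf("config sc_cutoff %s", fmt_num(cfg$sc_cutoff)),
    sprintf("config bb_cutoff %s", fmt_num(cfg$bb_cutoff)),
    paste("config sc_n", paste(cfg$sc_n, collapse = " ")),
    paste("config bb_n", paste(cfg$bb_n, collapse = " ")),
    sprintf("config env_n %d", cfg$env_n),
    sprintf("config env_max %s", fmt_num(cfg$env_max)),
    sprintf("config rama_n %d", cfg$rama_n),
    sprintf("scalar sheet_bias %s", fmt_num(pset$sheet_bias)),
    sprintf("scalar hbond_magnitude %s", fmt_num(pset$hbond$magnitude))
  )
  blk_lines <- function(tag, k, pp) c(
    sprintf("%s %d kappa %s", tag, k, fmt_num(pp$kappa)),
    sprintf("%s %d radial %s", tag, k,
            paste(fmt_num(pp$radial$coef), collapse = " ")),
    sprintf("%s %d angular %s", tag, k,
            paste(fmt_num(pp$angular$coef), collapse = " ")),
    sprintf("%s %d ang1 %s", tag, k,
            paste(fmt_num(pp$ang1$coef), collapse = " ")),
    sprintf("%s %d ang2 %s", tag, k,
            paste(fmt_num(pp$ang2$coef), collapse = " ")))
  for (k in seq_along(pset$sc_pairs))
    lines <- c(lines, blk_lines("sc_pair", k, pset$sc_pairs[[k]]))
  for (k in seq_along(pset$bb_pairs))
    lines <- c(lines, blk_lines("bb_pair", k, pset$bb_pairs[[k]]))
  for (a in names(pset$env))
    lines <- c(lines, sprintf("env %s %s", a,
                              paste(fmt_num(pset$env[[a]]$coef),
                                    collapse = " ")))
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' Read a parameter set from a text file
#'
#' Parses a file written by [write_params()], validating the version header
#' and every block count; a malformed file raises `cg_schema_error` naming
#' the offending block, and an unknown version raises
#' `cg_unsupported_version_error`.
#'
#' @param path input file path.
#' @return a `cg_params` bit-identical to the one written.
#' @export
read_params <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^cgfold-params v[0-9]+$", lines[1]))
    cg_error("cg_schema_error", "missing cgfold-params header",
             block = "header")
  version <- as.integer(sub("^cgfold-params v", "", lines[1]))
  if (version != 1L)
    cg_error("cg_unsupported_version_error",
             sprintf("unsupported parameter file version %d", version))
  toks <- strsplit(lines[-1], " +")
  cfg <- PARAM_DEFAULT_CONFIG
  sc <- replicate(210, list(), simplify = FALSE)
  bb <- replicate(100, list(), simplify = FALSE)
  env <- stats::setNames(vector("list", 20), AA_CODES)
  sheet_bias <- NULL; hbond_magnitude <- NULL
  for (tk in toks) {
    if (!length(tk) || tk[1] == "#") next
    kind <- tk[1]
    if (kind == "config") {
      key <- tk[2]
      val <- parse_nums(tk[-(1:2)], length(tk) - 2L, key, "config")
      if (key %in% c("sc_n", "bb_n")) {
        if (length(val) != 4)
          cg_error("cg_schema_error", paste(key, "needs 4 counts"),
                   block = "config")
        cfg[[key]] <- stats::setNames(as.integer(val),
                                      c("radial", "angular", "ang1", "ang2"))
      } else if (key %in% c("env_n", "rama_n")) {
        cfg[[key]] <- as.integer(val)
      } else if (key %in% c("sc_cutoff", "bb_cutoff", "env_max")) {
        cfg[[key]] <- val
      } else {
        cg_error("cg_schema_error", paste("unknown config key", key),
                 block = "config")
      }
    } else if (kind == "scalar") {
      val <- parse_nums(tk[3], 1L, tk[2], "scalars")
      if (tk[2] == "sheet_bias") sheet_bias <- val
      else if (tk[2] == "hbond_magnitude") hbond_magnitude <- val
      else cg_error("cg_schema_error", paste("unknown scalar", tk[2]),
                    block = "scalars")
    } else if (kind %in% c("sc_pair", "bb_pair")) {
      block <- if (kind == "sc_pair") "sc_pairs" else "bb_pairs"
      kmax <- if (kind == "sc_pair") 210L else 100L
      ntab <- if (kind == "sc_pair") cfg$sc_n else cfg$bb_n
      k <- suppressWarnings(as.integer(tk[2]))
      if (is.na(k) || k < 1L || k > kmax)
        cg_error("cg_schema_error",
                 sprintf("%s index '%s' out of range 1..%d", kind, tk[2],
                         kmax), block = block)
      part <- tk[3]
      want <- if (part == "kappa") 1L else ntab[[part]]
      if (is.null(want))
        cg_error("cg_schema_error", paste("unknown curve", part),
                 block = block)
      val <- parse_nums(tk[-(1:3)], want,
                        sprintf("%s %d %s", kind, k, part), block)
      if (kind == "sc_pair") sc[[k]][[part]] <- val
      else bb[[k]][[part]] <- val
    } else if (kind == "env") {
      a <- tk[2]
      if (!a %in% AA_CODES)
        cg_error("cg_schema_error", paste("unknown residue code", a),
                 block = "env")
      env[[a]] <- parse_nums(tk[-(1:2)], cfg$env_n, paste("env", a), "env")
    } else {
      cg_error("cg_schema_error", paste("unknown record type", kind),
               block = kind)
    }
  }
  check_blocks <- function(lst, block) {
    ok <- vapply(lst, function(b)
      all(c("kappa", "radial", "angular", "ang1", "ang2") %in% names(b)), TRUE)
    if (!all(ok))
      cg_error("cg_schema_error",
               sprintf("%s block %d is incomplete", block, which(!ok)[1]),
               block = block)
  }
  check_blocks(sc, "sc_pairs")
  check_blocks(bb, "bb_pairs")
  if (any(vapply(env, is.null, TRUE)))
    cg_error("cg_schema_error",
             sprintf("missing env curve for %s",
                     AA_CODES[which(vapply(env, is.null, TRUE))[1]]),
             block = "env")
  if (is.null(sheet_bias) || is.null(hbond_magnitude))
    cg_error("cg_schema_error", "missing trainable scalar", block = "scalars")
  new_parameter_set(sc = sc, bb = bb, env = env, sheet_bias = sheet_bias,
                    hbond_magnitude = hbond_magnitude, config = cfg)
}

#' Rotamer library text files
#'
#' `write_rotamer_library()` serializes a rotamer library (as returned by
#' [default_rotamer_library()]) to a versioned text file, one state per line:
#' residue code, weight, local position (3), local orientation (3).
#' `read_rotamer_library()` parses it back bit-exactly, validating that every
#' canonical residue has 1-6 states with positive weights (renormalized to
#' sum to one) and unit orientations.
#'
#' @param rotlib a rotamer library list.
#' @param path file path.
#' @return `write_rotamer_library()` returns `path` invisibly;
#'   `read_rotamer_library()` returns the library.
#' @export
write_rotamer_library <- function(rotlib, path) {
  lines <- "cgfold-rotamers v1"
  for (a in names(rotlib)) {
    e <- rotlib[[a]]
    for (s in seq_along(e$w))
      lines <- c(lines, sprintf("state %s %s %s %s", a, fmt_num(e$w[s]),
                                paste(fmt_num(e$pos[s, ]), collapse = " "),
                                paste(fmt_num(e$ori[s, ]), collapse = " ")))
  }
  tmp <- tempfile(tmpdir = dirname(path))
  writeLines(lines, tmp)
  file.rename(tmp, path)
  invisible(path)
}

#' @rdname write_rotamer_library
#' @export
read_rotamer_library <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^cgfold-rotamers v[0-9]+$", lines[1]))
    cg_error("cg_schema_error", "missing cgfold-rotamers header",
             block = "header")
  version <- as.integer(sub("^cgfold-rotamers v", "", lines[1]))
  if (version != 1L)
    cg_error("cg_unsupported_version_error",
             sprintf("unsupported rotamer file version %d", version))
  lib <- list()
  for (tk in strsplit(lines[-1], " +")) {
    if (!length(tk) || tk[1] == "#") next
    if (tk[1] != "state" || length(tk) != 9)
      cg_error("cg_schema_error", "malformed rotamer state line",
               block = "states")
    a <- tk[2]
    if (!a %in% AA_CODES)
      cg_error("cg_schema_error", paste("unknown residue code", a),
               block = "states")
    v <- parse_nums(tk[3:9], 7L, paste("state", a), "states")
    e <- lib[[a]]
    if (is.null(e)) e <- list(pos = NULL, ori = NULL, w = numeric(0))
    e$w <- c(e$w, v[1])
    e$pos <- rbind(e$pos, v[2:4])
    e$ori <- rbind(e$ori, v[5:7])
    lib[[a]] <- e
  }
  missing <- setdiff(AA_CODES, names(lib))
  if (length(missing))
    cg_error("cg_schema_error",
             paste("missing rotamer states for", missing[1]),
             block = "states")
  for (a in names(lib)) {
    e <- lib[[a]]
    if (length(e$w) > 6L)
      cg_error("cg_schema_error",
               sprintf("residue %s has %d states (maximum 6)", a,
                       length(e$w)), block = "states")
    if (any(e$w <= 0))
      cg_error("cg_schema_error",
               sprintf("residue %s has a non-positive weight", a),
               block = "states")
    nrm <- sqrt(rowSums(e$ori^2))
    if (any(abs(nrm - 1) > 1e-6))
      cg_error("cg_schema_error",
               sprintf("residue %s has a non-unit orientation", a),
               block = "states")
    e$w <- e$w / sum(e$w)
    rownames(e$pos) <- rownames(e$ori) <- NULL
    lib[[a]] <- e
  }
  lib[AA_CODES]
}
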