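# File formats: PDB (through bio3d), XYZ trajectories, the HILLS/COLVAR
# whitespace dialects, and the flat key = value run configuration.

#' Read a PDB file as conformation(s)
#'
#' @param path file path.
#' @param multi if `TRUE`, read all MODEL blocks and return a list of
#'   conformations (in file order); otherwise the first model.
#' @return a [conformation()] or a list of them.
#' @export
read_pdb <- function(path, multi = FALSE) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = multi, verbose = FALSE),
                  error = function(e)
                    abort_ap(sprintf("cannot parse PDB '%s': %s", path,
                                     conditionMessage(e)),
                             "actipath_parse_error"))
  at <- pdb$atom
  # first altloc kept, as documented
  if (!is.null(at$alt) && any(!is.na(at$alt) & at$alt != "")) {
    keep <- is.na(at$alt) | at$alt %in% c("", "A")
    if (!all(keep)) warning("alternate locations present; keeping the first")
    at <- at[keep, , drop = FALSE]
  }
  mk <- function(xyz) conformation(matrix(xyz, ncol = 3, byrow = TRUE),
                                   atom_names = at$elety,
                                   residue_ids = at$resno,
                                   residue_names = at$resid,
                                   chain_ids = ifelse(is.na(at$chain), "A", at$chain))
  if (multi && is.matrix(pdb$xyz) && nrow(pdb$xyz) > 1L)
    lapply(seq_len(nrow(pdb$xyz)), function(i) mk(pdb$xyz[i, ]))
  else mk(pdb$xyz[1, ])
}

#' Write conformation(s) as a PDB file
#'
#' Multi-model output (MODEL/ENDMDL blocks) when given a list.
#'
#' @param conf a [conformation()] or list of conformations sharing one
#'   topology.
#' @param path file path.
#' @export
write_pdb <- function(conf, path) {
  confs <- if (inherits(conf, "conformation")) list(conf) else conf
  c1 <- confs[[1]]
  n <- nrow(c1$coords)
  xyz <- do.call(rbind, lapply(confs, function(cf) as.numeric(t(cf$coords))))
  bio3d::write.pdb(file = path, xyz = xyz, type = rep("ATOM", n),
                   resno = c1$residue_ids, resid = c1$residue_names,
                   chain = c1$chain_ids, elety = c1$atom_names,
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read / write XYZ trajectories
#'
#' Plain XYZ: per frame a line with the atom count, a comment line, then
#' `name x y z` records.  Coordinates at %.9g so round trips are exact at
#' displayed precision.
#'
#' @param path file path.
#' @param template optional [conformation()] supplying residue/chain
#'   annotation for the frames read.
#' @return list of conformations.
#' @export
read_xyz <- function(path, template = NULL) {
  lines <- readLines(path)
  out <- list(); i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n))
      abort_ap(sprintf("XYZ parse error at line %d: expected atom count", i),
               "actipath_parse_error")
    if (i + 1L + n > length(lines))
      abort_ap("truncated XYZ frame", "actipath_parse_error")
    rec <- strsplit(trimws(lines[(i + 2L):(i + 1L + n)]), "[[:space:]]+")
    nm <- vapply(rec, `[[`, "", 1L)
    co <- t(vapply(rec, function(r) as.numeric(r[2:4]), numeric(3)))
    cf <- if (!is.null(template)) {
      stopifnot(nrow(template$coords) == n)
      template$coords <- co
      template
    } else conformation(co, atom_names = nm)
    out[[length(out) + 1L]] <- cf
    i <- i + 2L + n
  }
  out
}

#' @rdname read_xyz
#' @param confs a conformation or list of conformations.
#' @param comment per-frame comment (recycled).
#' @export
write_xyz <- function(confs, path, comment = "") {
  if (inherits(confs, "conformation")) confs <- list(confs)
  con <- file(path, "w"); on.exit(close(con))
  comment <- rep_len(comment, length(confs))
  for (i in seq_along(confs)) {
    cf <- confs[[i]]
    writeLines(c(as.character(nrow(cf$coords)), comment[i]), con)
    writeLines(sprintf("%s %s %s %s", cf$atom_names,
                       fmt_g(cf$coords[, 1]), fmt_g(cf$coords[, 2]),
                       fmt_g(cf$coords[, 3])), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# HILLS / COLVAR dialects: whitespace tables with a "#! FIELDS ..." header
# and optional "#! SET key value" metadata lines.  Numerics at %.9g.
# ---------------------------------------------------------------------------

write_fields_file <- function(df, path, meta = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(names(df), collapse = " ")), con)
  for (k in names(meta))
    writeLines(sprintf("#! SET %s %s", k, as.character(meta[[k]])), con)
  if (nrow(df))
    writeLines(do.call(paste, lapply(df, fmt_g)), con)
  invisible(path)
}

read_fields_file <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#! FIELDS"))
    abort_ap(sprintf("'%s': missing '#! FIELDS' header", path),
             "actipath_parse_error")
  fields <- strsplit(sub("^#! FIELDS +", "", lines[1]), "[[:space:]]+")[[1]]
  meta <- list()
  body <- character(0)
  for (ln in lines[-1]) {
    if (startsWith(ln, "#! SET")) {
      kv <- strsplit(sub("^#! SET +", "", ln), "[[:space:]]+")[[1]]
      meta[[kv[1]]] <- paste(kv[-1], collapse = " ")
    } else if (!startsWith(ln, "#") && nzchar(trimws(ln)))
      body <- c(body, ln)
  }
  if (length(body)) {
    toks <- strsplit(trimws(body), "[[:space:]]+")
    bad <- which(lengths(toks) != length(fields))
    if (length(bad))
      abort_ap(sprintf("'%s': row %d has %d values for %d fields", path,
                       bad[1], lengths(toks)[bad[1]], length(fields)),
               "actipath_parse_error")
    df <- as.data.frame(lapply(seq_along(fields), function(j)
      as.numeric(vapply(toks, `[[`, "", j))))
  } else df <- as.data.frame(matrix(numeric(0), 0, length(fields)))
  names(df) <- fields
  attr(df, "meta") <- meta
  df
}

#' Write / read a HILLS file
#'
#' Header `#! FIELDS time <cvs> sigma_<cvs> height biasf`; metadata lines
#' (`#! SET`) record the package version and seed when available.
#'
#' @param hills hills data.frame (e.g. `run$hills`).
#' @param path file path.
#' @param meta named list of metadata to record.
#' @export
write_hills <- function(hills, path, meta = NULL) {
  write_fields_file(hills, path, meta)
}

#' @rdname write_hills
#' @return `read_hills`: the hills data.frame, with metadata in
#'   `attr(, "meta")`.
#' @export
read_hills <- function(path) read_fields_file(path)

#' Rebuild a bias state from a hills table
#'
#' @param hills hills data.frame with columns `time`, CV centers,
#'   `sigma_<cv>`, `height`, `biasf`.
#' @param cfg optional [wt_config()]; reconstructed from the table's sigma
#'   and biasf columns (at `temperature`) when omitted.
#' @param temperature temperature in K used for the reconstruction.
#' @return a [bias_state()].
#' @export
as_bias_state <- function(hills, cfg = NULL, temperature = 300) {
  signames <- grep("^sigma_", names(hills), value = TRUE)
  cvn <- sub("^sigma_", "", signames)
  if (is.null(cfg)) {
    if (!nrow(hills))
      abort_ap("cannot reconstruct a bias state from an empty hills table without 'cfg'")
    biasf <- if (!is.null(hills$biasf) && is.finite(hills$biasf[1]))
      hills$biasf[1] else Inf
    delta_T <- if (is.finite(biasf) && biasf > 1) (biasf - 1) * temperature else Inf
    tau <- if (nrow(hills) >= 2L) max(hills$time[2] - hills$time[1], 1e-9) else 1
    cfg <- wt_config(w = max(hills$height, 0.4), tau = tau,
                     delta_T = delta_T, temperature = temperature,
                     sigma = stats::setNames(as.numeric(hills[1, signames]), cvn))
  }
  st <- bias_state(cfg, cvn)
  st$hills <- hills[, c("time", cvn, signames, "height", "biasf")]
  st
}

#' Write / read a COLVAR file
#'
#' Header `#! FIELDS time <columns>`; all frame-table columns are
#' preserved in order.
#'
#' @param frames frame data.frame (e.g. `run$frames`).
#' @param path file path.
#' @param meta named list of metadata (`#! SET`) lines.
#' @export
write_colvar <- function(frames, path, meta = NULL) {
  write_fields_file(frames, path, meta)
}

#' @rdname write_colvar
#' @return `read_colvar`: the frame data.frame with metadata in
#'   `attr(, "meta")`.
#' @export
read_colvar <- function(path) read_fields_file(path)

# ---------------------------------------------------------------------------
# Flat key = value run configuration with the field's canonical defaults.
# ---------------------------------------------------------------------------

#' Default run configuration
#'
#' All biasing, path, clustering and fixture parameters with their
#' canonical defaults: hill height w = 0.4 kcal/mol, deposition interval
#' tau = 8 ps, dT = 10 T at T = 300 K, sigma_s = 0.1, sigma_z = 1 A^2,
#' gamma = 4 1/A^2, ratchet k = 10 kcal/(mol nm^2), 10 ratchet runs, tree
#' cut at 30 clusters, 10 references.
#'
#' @return named list of class `"run_config"`.
#' @export
default_run_config <- function() {
  structure(list(w = 0.4, tau = 8, delta_T_over_T = 10, temperature = 300,
                 sigma_s = 0.1, sigma_z = 1, gamma = 4, k_ratchet = 10,
                 n_abmd = 10, k_cut = 30, n_refs = 10, seed = 1,
                 steps = 20000, dt = 0.01, friction = 1, stride = 10,
                 barrier = 3, asymmetry = 1, receptor_seed = 1),
            class = "run_config")
}

#' Read / write the flat key = value configuration
#'
#' Lines of the form `key = value` (or `key value`); `#` comments ignored.
#' Unknown keys are rejected; missing keys take the defaults of
#' [default_run_config()].
#'
#' @param path file path.
#' @return a `"run_config"` list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  lines <- readLines(path)
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    if (!nzchar(trimws(ln))) next
    kv <- strsplit(trimws(ln), "[[:space:]]*=[[:space:]]*|[[:space:]]+")[[1]]
    if (length(kv) != 2L)
      abort_ap(sprintf("config line %d: expected 'key = value'", i),
               "actipath_parse_error")
    if (!kv[1] %in% names(cfg))
      abort_ap(sprintf("unknown config key '%s'", kv[1]),
               "actipath_config_error")
    val <- suppressWarnings(as.numeric(kv[2]))
    if (is.na(val))
      abort_ap(sprintf("config key '%s': non-numeric value '%s'", kv[1], kv[2]),
               "actipath_config_error")
    cfg[[kv[1]]] <- val
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg a `"run_config"` list.
#' @export
write_run_config <- function(cfg, path) {
  writeLines(sprintf("%s = %s", names(cfg),
                     vapply(unclass(cfg), fmt_g, "")), path)
  invisible(path)
}

# short stable hash of a config (for output-file headers)
config_hash <- function(cfg) {
  s <- paste(names(cfg), vapply(unclass(cfg), fmt_g, ""), collapse = ";")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% .Machine$integer.max)
}

# standard metadata block for output files
run_meta <- function(cfg = NULL, seed = NULL) {
  m <- list(generator = paste0("actipath ",
                               as.character(utils::packageVersion("actipath"))))
  if (!is.null(cfg)) m$config_hash <- config_hash(cfg)
  if (!is.null(seed)) m$seed <- as.integer(seed)
  m
}
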