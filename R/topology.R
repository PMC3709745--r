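# GROMACS include-topology (.itp) output and input for elastic networks,
# plus the membrane-setup lipid-count arithmetic.

#' Write an elastic network as a GROMACS [ bonds ] section
#'
#' Emits function-type-1 harmonic bonds (1-based bead indices, rest
#' length in nm to 5 decimals, force constant as given) in a standalone
#' include file. A header comment records the generator parameters and
#' per-origin spring counts; each row carries its origin as a trailing
#' comment so a round trip through [read_itp()] is lossless.
#'
#' @param net an `elastic_network` (non-empty).
#' @param molname molecule name recorded in the header.
#' @param path output path.
#' @param ifdef_guard optional preprocessor symbol; when given, the bonds
#'   section is wrapped in `#ifdef`/`#endif`.
#' @return invisibly, `path`.
#' @export
write_itp <- function(net, molname, path, ifdef_guard = NULL) {
  sp <- net$springs
  if (nrow(sp) == 0) stop("refusing to write an empty bonds section")
  if (any(sp$b0 <= 0)) stop("non-positive rest length in network")
  p <- net$params
  fmt_k <- function(k) {
    ifelse(k == round(k), format(k, scientific = FALSE, trim = TRUE),
           sprintf("%.3f", k))
  }
  hdr <- c(
    sprintf("; elastic network for molecule %s", molname),
    if (!is.null(p)) sprintf(
      "; params: SA_c=%s%% R_c=%s nm K_SPRING=%s kJ/mol/nm^2 mode=%s",
      p$sa_c, p$r_c, p$k_spring, p$mode),
    sprintf("; springs: total=%d hbond=%d sa=%d elnedyn=%d",
            nrow(sp), sum(sp$origin == "hbond"), sum(sp$origin == "sa"),
            sum(sp$origin == "elnedyn"))
  )
  rows <- sprintf("%5d %5d %5d %10.5f %s ; %s",
                  sp$i, sp$j, 1L, sp$b0, fmt_k(sp$k), sp$origin)
  body <- c("[ bonds ]", "; i     j     funct   b0(nm)   k", rows)
  if (!is.null(ifdef_guard)) {
    body <- c(paste("#ifdef", ifdef_guard), body, "#endif")
  }
  con <- tryCatch(file(path, "w"), error = function(e) {
    stop("cannot write to ", path, ": ", conditionMessage(e))
  })
  on.exit(close(con))
  writeLines(c(hdr, "", body), con)
  invisible(path)
}

#' Read an elastic network from a GROMACS include file
#'
#' Parses the `[ bonds ]` section tolerantly (comments, blank lines and
#' `#ifdef` guards are skipped). Spring origins are restored from the
#' per-row comments written by [write_itp()] when present, otherwise
#' tagged `"unknown"`. Rows with a function type other than 1 are kept
#' with a warning.
#'
#' @param path path to an .itp file with a bonds section.
#' @return an `elastic_network` (springs only; no model attached).
#' @export
read_itp <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  in_bonds <- FALSE
  rows <- list()
  warned_funct <- FALSE
  for (ln_no in seq_along(lines)) {
    raw <- lines[ln_no]
    code <- sub(";.*$", "", raw)
    comment <- if (grepl(";", raw, fixed = TRUE)) {
      trimws(sub("^[^;]*;[ \t]*", "", raw))
    } else ""
    code <- trimws(code)
    if (!nzchar(code)) next
    if (startsWith(code, "#")) next
    if (grepl("^\\[", code)) {
      in_bonds <- grepl("^\\[\\s*bonds\\s*\\]$", code)
      next
    }
    if (!in_bonds) next
    f <- strsplit(code, "\\s+")[[1]]
    if (length(f) < 5) {
      stop("malformed bonds row at line ", ln_no, ": ", raw)
    }
    v <- suppressWarnings(as.numeric(f[1:5]))
    if (any(is.na(v))) {
      stop("malformed bonds row at line ", ln_no, ": ", raw)
    }
    if (v[3] != 1 && !warned_funct) {
      warning("bonds row(s) with function type != 1 kept as-is")
      warned_funct <- TRUE
    }
    origin <- if (comment %in% c("hbond", "sa", "elnedyn")) comment else {
      "unknown"
    }
    rows[[length(rows) + 1]] <- data.frame(
      i = as.integer(v[1]), j = as.integer(v[2]), b0 = v[4], k = v[5],
      origin = origin, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) stop("no bonds section in ", path)
  elastic_network(do.call(rbind, rows))
}

#' Lipid count for a membrane patch
#'
#' Number of lipids for one leaflet of an XY box surface, assuming 256
#' lipids cover approximately 100 nm^2: `floor(box_x * box_y * 256 /
#' 100)`. Callers double the result for a bilayer.
#'
#' @param box_x,box_y box edge lengths in nm (positive).
#' @return integer lipid count.
#' @export
lipid_count <- function(box_x, box_y) {
  if (box_x <= 0 || box_y <= 0) stop("box dimensions must be positive")
  as.integer(floor(box_x * box_y * 256 / 100))
}
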