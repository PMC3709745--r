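# Parser for Stride plain-text reports: per-residue solvent accessibility
# (ASG records) and backbone hydrogen bonds (ACC/DNR records). The common
# report layout is accepted; Stride versions differ slightly in trailing
# columns, which are ignored.

#' Parse a Stride report
#'
#' Reads per-residue absolute solvent accessibility and the backbone
#' hydrogen-bond list from a Stride output file generated for `structure`,
#' so that the externally computed values can drive network construction
#' in place of the package's own engines.
#'
#' @param path path to a Stride report.
#' @param structure the [structure3d] the report was computed for; Stride
#'   residues are matched to it by chain and author residue number.
#'
#' @details `ASG` lines supply the absolute accessible area (A^2, 10th
#'   field) and the secondary-structure code (6th field). Hydrogen bonds
#'   are taken from `DNR`/`ACC` lines (`DNR donor -> acceptor`,
#'   `ACC acceptor -> donor`) and de-duplicated into undirected residue
#'   pairs.
#'
#' @return an object of class `stride_record`: list with `sa` (named
#'   numeric, A^2, names = `res_uid`), `ss` (named character), and
#'   `hbonds` (data.frame `donor`, `acceptor` in `res_uid` terms).
#' @export
parse_stride <- function(path, structure) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)

  res <- structure$residues
  lookup <- function(chain, resno, what) {
    hit <- which(res$chain == chain & res$resno == resno)
    if (length(hit) == 0) {
      stop("Stride ", what, " references residue ", chain, ":", resno,
           " absent from structure")
    }
    res$res_uid[hit[1]]
  }

  asg <- lines[startsWith(lines, "ASG")]
  sa <- numeric(0)
  ss <- character(0)
  for (ln in asg) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    # ASG resid chain resno ordinal code ss_name phi psi area ...
    uid <- lookup(f[3], suppressWarnings(as.integer(f[4])), "ASG line")
    sa[as.character(uid)] <- as.numeric(f[10])
    ss[as.character(uid)] <- f[6]
  }
  if (any(!is.finite(sa)) || any(sa < 0)) {
    stop("invalid (negative or non-numeric) SA value in Stride report")
  }

  hb_lines <- lines[startsWith(lines, "DNR") | startsWith(lines, "ACC")]
  pairs <- matrix(integer(0), ncol = 2)
  for (ln in hb_lines) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    arrow <- which(f == "->")
    if (length(arrow) != 1) next
    u1 <- lookup(f[3], suppressWarnings(as.integer(f[4])), "H-bond line")
    u2 <- lookup(f[arrow + 2], suppressWarnings(as.integer(f[arrow + 3])),
                 "H-bond line")
    d <- if (startsWith(ln, "DNR")) c(u1, u2) else c(u2, u1)
    pairs <- rbind(pairs, d)
  }
  hb <- if (nrow(pairs) > 0) {
    key <- paste(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    keep <- !duplicated(key)
    data.frame(donor = pairs[keep, 1], acceptor = pairs[keep, 2])
  } else {
    data.frame(donor = integer(0), acceptor = integer(0))
  }

  out <- list(sa = sa, ss = ss, hbonds = hb)
  class(out) <- "stride_record"
  out
}
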