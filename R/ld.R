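#' Linkage disequilibrium between two sites
#'
#' Haplotype-count based `D = p_AB - p_A p_B` and
#' `r2 = D^2 / (p_A(1-p_A) p_B(1-p_B))` for the "1" alleles of two
#' columns of a phased matrix (derived alleles once polarized). Always
#' computed within one population panel; pooling panels inflates LD
#' through structure.
#'
#' @param x `hap_matrix` restricted to one population.
#' @param site_a,site_b column indices or variant ids.
#' @return list `id_a, id_b, p_a, p_b, p_ab, D, r2`.
#' @examples
#' m <- matrix(c(1, 1, 0, 0, 1, 1, 0, 0), ncol = 2)
#' @export
r_squared <- function(x, site_a, site_b) {
  i <- resolve_site(x, site_a)
  j <- resolve_site(x, site_b)
  a <- x$data[, i]
  b <- x$data[, j]
  pa <- mean(a); pb <- mean(b)
  for (nm in c(i, j)) {
    p <- mean(x$data[, nm])
    if (p == 0 || p == 1)
      stopf("site %s is monomorphic in the selected haplotypes", x$sites$id[nm])
  }
  pab <- mean(a & b)
  D <- pab - pa * pb
  list(id_a = x$sites$id[i], id_b = x$sites$id[j], p_a = pa, p_b = pb,
       p_ab = pab, D = D, r2 = D^2 / (pa * (1 - pa) * pb * (1 - pb)))
}

resolve_site <- function(x, site) {
  if (is.character(site)) {
    i <- match(site, x$sites$id)
    if (is.na(i)) stopf("variant '%s' not found", site)
    i
  } else as.integer(site)
}

#' Phase relation between two specified alleles
#'
#' TRUE iff the given allele pair co-occurs on haplotypes more often than
#' expected under independence (D for that allele pair strictly
#' positive).
#'
#' @param x `hap_matrix`.
#' @param focal_site,partner_site column indices or ids.
#' @param focal_allele,partner_allele 0 or 1, naming which allele of each
#'   site is meant (1 = derived in a polarized matrix).
#' @export
phase_relation <- function(x, focal_site, focal_allele, partner_site,
                           partner_allele) {
  i <- resolve_site(x, focal_site)
  j <- resolve_site(x, partner_site)
  a <- if (focal_allele == 1) x$data[, i] else 1L - x$data[, i]
  b <- if (partner_allele == 1) x$data[, j] else 1L - x$data[, j]
  mean(a & b) - mean(a) * mean(b) > 0
}

#' Pairwise LD table for a set of sites
#'
#' @param x `hap_matrix` of one population.
#' @param sites vector of column indices or variant ids (>= 2).
#' @param population label copied into the table.
#' @return data.frame `id_a, id_b, population, p_a, p_b, p_ab, D, r2`.
#' @export
ld_table <- function(x, sites, population = NA_character_) {
  idx <- vapply(sites, resolve_site, integer(1), x = x)
  pairs <- utils::combn(idx, 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    ld <- r_squared(x, pairs[1, k], pairs[2, k])
    data.frame(id_a = ld$id_a, id_b = ld$id_b, population = population,
               p_a = ld$p_a, p_b = ld$p_b, p_ab = ld$p_ab, D = ld$D,
               r2 = ld$r2, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Haplotype-matrix display around a focal variant
#'
#' Orders haplotypes so that carriers of the focal derived allele sit
#' above non-carriers (the separator row index is recorded), sorts rows
#' lexicographically within each block, and keeps polymorphic columns in
#' positional order; 1 = derived, 0 = ancestral. The object renders as
#' text art (dark/light convention: `#` = derived, `.` = ancestral) and
#' can be plotted to an image file.
#'
#' @param x polarized `hap_matrix` of one population.
#' @param focal column index or id of the focal site.
#' @return Object of class `hap_report`: list with `matrix` (reordered
#'   0/1), `separator` (number of derived-carrier rows), `focal_col`
#'   (column of the focal site in the report), `positions`, `ids`.
#' @export
haplotype_matrix_report <- function(x, focal) {
  if (!x$polarized) stopf("haplotype report requires a polarized matrix")
  i <- resolve_site(x, focal)
  cs <- colSums(x$data)
  if (cs[i] == 0 || cs[i] == nrow(x$data))
    stopf("focal site %s is monomorphic", x$sites$id[i])
  keep <- which(cs > 0 & cs < nrow(x$data))
  m <- x$data[, keep, drop = FALSE]
  focal_col <- match(i, keep)
  carrier <- m[, focal_col] == 1L
  lex <- function(mm) {
    if (nrow(mm) <= 1) return(seq_len(nrow(mm)))
    order(apply(mm, 1, paste, collapse = ""))
  }
  top <- which(carrier)[lex(m[carrier, , drop = FALSE])]
  bot <- which(!carrier)[lex(m[!carrier, , drop = FALSE])]
  structure(list(matrix = m[c(top, bot), , drop = FALSE],
                 separator = length(top), focal_col = focal_col,
                 positions = x$sites$pos[keep], ids = x$sites$id[keep],
                 hap_ids = x$hap_ids[c(top, bot)]),
            class = "hap_report")
}

#' @export
format.hap_report <- function(x, ...) {
  rows <- apply(x$matrix, 1, function(r) paste(ifelse(r == 1, "#", "."), collapse = ""))
  sep <- paste(rep("-", ncol(x$matrix)), collapse = "")
  marker <- paste0(strrep(" ", x$focal_col - 1), "v")
  c(marker, rows[seq_len(x$separator)], sep,
    if (x$separator < length(rows)) rows[(x$separator + 1):length(rows)])
}

#' @export
print.hap_report <- function(x, ...) {
  cat(format(x), sep = "\n")
  invisible(x)
}

#' Render a haplotype report to an image file
#'
#' @param report `hap_report` from [haplotype_matrix_report()].
#' @param file output PNG path.
#' @export
plot_hap_report <- function(report, file) {
  grDevices::png(file, width = 640, height = 480)
  on.exit(grDevices::dev.off())
  m <- report$matrix[rev(seq_len(nrow(report$matrix))), , drop = FALSE]
  graphics::image(t(m), col = c("grey85", "grey25"), axes = FALSE,
                  main = "haplotypes (dark = derived)")
  graphics::abline(h = 1 - (report$separator - 0.5) / (nrow(report$matrix) - 1),
                   lwd = 3)
  invisible(file)
}

#' Parse the text rendering of a haplotype report
#'
#' Inverse of `format.hap_report` for the matrix content; used to verify
#' the rendering is lossless.
#'
#' @param lines character vector from [format()] of a `hap_report`.
#' @return list `matrix`, `separator`.
#' @export
parse_hap_report <- function(lines) {
  lines <- lines[-1]  # focal marker
  sep <- grep("^-+$", lines)
  body <- lines[setdiff(seq_along(lines), sep)]
  m <- do.call(rbind, lapply(strsplit(body, ""), function(ch) as.integer(ch == "#")))
  list(matrix = m, separator = if (length(sep)) sep - 1L else nrow(m))
}
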