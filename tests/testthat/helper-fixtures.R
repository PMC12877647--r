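# Shared fixture builders and independent brute-force oracles. The oracles
# deliberately re-derive every quantity with literal loops and explicit
# arithmetic, independent of the package's vectorized/grid code paths.

.fixture_cache <- new.env(parent = emptyenv())

# load (and memoize) a helix/extended/cavity fixture context
fixture_ctx <- function(n = 20, geometry = "helix", sequence = NULL,
                        seed = 1, site = NULL, mutation = "W") {
  key <- paste(n, geometry, paste(sequence, collapse = ""), seed,
               site %||% "", mutation)
  if (!is.null(.fixture_cache[[key]])) return(.fixture_cache[[key]])
  spec <- fixture_spec(seed = seed, n_residues = n, geometry = geometry,
                       sequence = sequence, site = site, mutation = mutation)
  path <- tempfile(fileext = ".pdb")
  make_structure(spec, path)
  ctx <- load_structure(path)
  .fixture_cache[[key]] <- ctx
  ctx
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# literal O(n^2) neighbor scan
bf_neighbors <- function(ctx, position, radius, chain = "A") {
  q <- ctx$atoms[ctx$atoms$chain == chain & ctx$atoms$resno == position, ]
  hits <- character(0)
  for (i in seq_len(nrow(ctx$atoms))) {
    a <- ctx$atoms[i, ]
    if (a$chain == chain && a$resno == position) next
    for (j in seq_len(nrow(q))) {
      d <- sqrt((a$x - q$x[j])^2 + (a$y - q$y[j])^2 + (a$z - q$z[j])^2)
      if (d <= radius) {
        hits <- c(hits, paste(a$chain, a$resno, sep = ":"))
        break
      }
    }
  }
  sort(unique(hits))
}

# literal clash/contact scan over rotamer side-chain atoms vs environment
bf_overlaps <- function(ctx, rot, cutoff, allowance) {
  env <- ctx$atoms[!(ctx$atoms$chain == rot$chain &
                     ctx$atoms$resno == rot$position), ]
  out <- character(0)
  for (i in seq_len(nrow(rot$atoms))) {
    p <- rot$atoms[i, ]
    for (j in seq_len(nrow(env))) {
      e <- env[j, ]
      d <- sqrt((p$x - e$x)^2 + (p$y - e$y)^2 + (p$z - e$z)^2)
      ov <- p$radius + e$radius - d
      if (p$elesy %in% c("N", "O") && e$elesy %in% c("N", "O")) {
        ov <- ov - allowance
      }
      if (ov >= cutoff) {
        out <- c(out, paste(p$name, e$chain, e$resno, e$elety))
      }
    }
  }
  sort(out)
}

# package results keyed the same way, for oracle comparison
clash_keys <- function(cl) {
  sort(paste(cl$atom, cl$chain, cl$resno, cl$partner))
}

# a hand-built placed rotamer (for arithmetic-level clash/contact tests)
fake_rotamer <- function(atoms, position = 999L, chain = "A") {
  structure(list(residue = "ALA", position = position, chain = chain,
                 chi = numeric(0), probability = 1, atoms = atoms,
                 anchors = NULL),
            class = "placed_rotamer")
}

# a context holding exactly the given atom table
fake_ctx <- function(atoms) {
  spscore:::new_struct_context(atoms)
}

atom_row <- function(elety, elesy, x, y, z, radius, chain = "A", resno = 1L,
                     resid = "ALA") {
  data.frame(chain = chain, resno = resno, resid = resid, elety = elety,
             elesy = elesy, x = x, y = y, z = z, radius = radius,
             stringsAsFactors = FALSE)
}

all_pairs <- local({
  aa <- names(spscore::AA_CODES)
  expand.grid(wt = aa, mut = aa, stringsAsFactors = FALSE)
})
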