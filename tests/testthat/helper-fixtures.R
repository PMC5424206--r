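## Lazily computed shared fixtures; each is built once per test run.
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

fx_models <- function() fixture("models", function() make_family_models(1L))
fx_metagenome <- function() fixture("mg", function()
  generate_metagenome(models = fx_models(), seed = 1L))
fx_proteins <- function() {
  mg <- fx_metagenome()
  stats::setNames(mg$proteins$residues, mg$proteins$id)
}

## small two-clade family used by several tests
fx_two_clades <- function() fixture("two_clades", function() {
  fs <- realize_family(family_model("F", 150, c(4, 4), 0.06, 0.7), 11L)
  stats::setNames(fs$members$residues, fs$members$id)
})

rand_protein <- function(n) paste(sample(sepmine:::AA20, n, TRUE), collapse = "")

## hand-built alignment around the synthetic SepCysS reference for exact
## worked examples; the reference is reference-like at every rule site
ref_msa_fixture <- function() {
  ref <- fx_models()$SepCysS$root           # 390 aa, no gaps
  n <- nchar(ref)
  ## member with the 8-residue deletion adjacent to the 234/235 junction
  del8 <- paste0(substr(ref, 1, 226), strrep("-", 8), substr(ref, 235, n))
  ## member with the 144-147 loop deleted
  noloop <- paste0(substr(ref, 1, 143), "----", substr(ref, 148, n))
  ## member lacking all three persulfide cysteines
  nocys <- ref
  for (p in sepmine:::SEPCYSS_PERSULFIDE)
    substr(nocys, p, p) <- "S"
  msa_from_alignment(c(ref = ref, del8 = del8, noloop = noloop,
                       nocys = nocys))
}

## deterministic 75-nt tRNA with a GCA anticodon at 34-36
make_trna_fixture <- function(n37) {
  x <- rep("A", 75)
  x[34:36] <- c("G", "C", "A")
  x[37] <- n37
  paste(x, collapse = "")
}
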