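# ecfpPool

Substructure pooling for extended-connectivity fingerprints in R.

## The problem

Extended-connectivity fingerprints (ECFPs) turn a molecule
$\mathcal{M}$ into a *set* of hashed integer identifiers,

$$\varphi(\mathcal{M}) = \{\mathcal{J}_1,\ldots,\mathcal{J}_k\} \subseteq \{1,\ldots,2^{32}\},$$

one identifier per circular substructure up to a maximal diameter $D$.
Before a machine-learning model can use them, these sets must be pooled
into fixed-length binary vectors by some set function
$\Psi : P(\mathfrak{J}) \to \{0,1\}^L$. The near-universal default is
**hash-based folding** — bit $i$ is set iff some identifier satisfies
$h(\mathcal{J}) = i$ — which inevitably collides distinct substructures
onto shared bits once $L < m_{\mathfrak{T}}$, the number of unique
substructures in the training set. Bit collisions blur both
interpretability and predictive signal.

`ecfpPool` implements this pooling framework for R, with four
interchangeable operators that calibrate on a training set and then
vectorise any compound:

- **folded** — classical hash-based folding, $h(\mathcal{J}) =
  (\mathcal{J} \bmod L) + 1$; training-set agnostic.
- **sort_slice** — *Sort & Slice*: rank all training substructures by
  their support count $c(\mathcal{J})$ (the number of training
  compounds containing $\mathcal{J}$; ties broken by the identifier
  order), keep the $L$ most frequent, and emit their one-hot presence
  vector. Collision-free by construction, and — because almost all
  substructures occur in fewer than half of the compounds — equivalent
  to selecting the columns with maximal Shannon entropy.
- **filtered** — supervised selection: drop singleton-support
  substructures, drop *non-closed* substructures (those containing a
  same-support substructure as a proper subgraph of their atom
  environment), then keep the $L$ features with the strongest
  $\chi^2$ dependence on the (binarised) label.
- **mim** — mutual-information maximisation: collapse
  identical-support features, then keep the $L$ features with the
  highest plug-in mutual information with the label.

The package also ships compound standardisation/desalting, circular
substructure enumeration with standard or pharmacophoric atomic
invariants (OpenBabel supplies SMILES parsing and canonicalisation; the
Morgan-style environment hashing is native), information-theoretic
diagnostics, a synthetic library generator with planted substructure
signal, and a cross-validated random-forest benchmarking harness with
random, stratified and Bemis–Murcko scaffold splits.

## Worked example

```r
library(ecfpPool)

lib   <- generateLibrary(fixtureSpec(nCompounds = 100, seed = 42))
clean <- cleanCompounds(lib, seed = 1)
sets  <- enumerateSubstructures(clean, enumConfig(maxDiameter = 4))
vocab <- buildVocabulary(sets)
frequencyStats(vocab)
#> Substructure-frequency summary (m_T = 752 over n = 100 compounds)
#>   support == 1      :  59.3%
#>   support <= 10     :  93.9%
#>   support <= 100    : 100.0%
#>   support <  n/2    : 98.40%
#>   support >  n/2    : 12 substructures
#>   support >= 0.9 n  : 2 substructures
```

The heavy tail is the point: 59% of the 752 substructures occur in a
single compound and almost none in more than half, so slicing away
infrequent substructures loses almost no information.

```r
cal <- calibratePooler(vocab, "sort_slice", L = 128)
fp  <- poolFingerprints(cal, sets)   # 100 x 128 binary matrix,
dim(fp)                              # one owned substructure per column
#> [1] 100 128
```

With $m_{\mathfrak{T}} = 752 \gg L = 64$, folding collides heavily and
Sort & Slice wins the cross-validated comparison (2-fold CV, 3 seeds,
random forests, planted-signal regression labels):

```r
reg <- plantLabels(clean, c(CCO = 1, `C(SC)` = 2), noiseSd = 0.3,
                   task = "regression", seed = 5)
res <- runBenchmark(reg, methods = c("folded", "sort_slice"),
                    lengths = 64L, diameters = 4L, seeds = 1:3)
summarizeBenchmark(res)
#>     dataset scheme model     method D invariants  L metric  mean     sd nRuns
#> 1 synthetic random    rf     folded 4   standard 64    mae 0.519 0.0720     6
#> 2 synthetic random    rf sort_slice 4   standard 64    mae 0.428 0.0773     6
```

A lower mean absolute error for `sort_slice` at the same fingerprint
length means the collision-free, frequency-ranked bits carry more
usable structural signal than the hashed ones.

A thin command-line interface over the same functions is installed at
`exec/ecfppool` (subcommands `clean`, `enumerate`, `stats`,
`featurise`, `synth`, `benchmark`).

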