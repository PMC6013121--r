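# fkrnet

Topological characterisation, recursive module decomposition and
key-regulator identification for gene–gene interaction networks with a
hierarchical scale-free organisation.

Disease interactomes — breast-cancer protein–protein interaction networks
being the motivating case — typically show heavy-tailed degree
distributions together with degree-dependent clustering, the signature of
*hierarchical* rather than plain scale-free organisation. In such networks
no single hub controls the system: modules nested across levels carry the
regulation, and only a few hubs stay influential all the way from the whole
network down to individual triangle motifs. fkrnet provides the complete
analysis pipeline for making those statements quantitative, for anyone
studying modular organisation and candidate regulator genes in undirected
interaction networks.

## What it computes

* **Topology.** Per node and per degree class: degree distribution
  $P(k) = n_k/N$, clustering $C = 2e_i/k_i(k_i-1)$, mean neighbour degree
  $C_n(k)$, normalised betweenness, per-component closeness, and
  eigenvector centrality (power iteration, unit L2 norm).
* **Power-law fits.** Discrete maximum likelihood with KS-selected lower
  cutoff and semiparametric bootstrap goodness-of-fit for $P(k)$
  (Clauset–Shalizi–Newman procedure, implemented in-package); log–log least
  squares with residual-bootstrap lack-of-fit for degree-aggregated curves.
  Together they yield the exponent sextet
  $(\gamma, \alpha, \beta, \epsilon, \delta, \mu)$ for
  $(P, C, C_n, C_B, C_C, C_E)$, plus a direct check of the fractal scaling
  relation $y(\lambda k)/y(k) = \lambda^D$.
* **Knockout.** Cumulative removal of leading hubs (degree-ranked,
  deterministic ties) with the full sextet refitted on each surviving
  network.
* **Module tree.** Recursive leading-eigenvector decomposition
  (implemented in-package: sign-splits of the modularity matrix
  $B = A - kk^\top/2m$) applied standalone to each qualifying module until
  only triangle motifs, triangle-free modules, or indivisible modules
  remain; per-level modularity per node.
* **Fundamental key regulators (FKRs).** Leading hubs whose branch lies in
  triangle-containing modules at every level and terminates in a motif,
  with per-level regulating probability $P_{FKR} = x^{[s]}/N^{[s]}$.
* **LCP compactness.** Common neighbours (CN) and local community links
  (LCL) per edge, LCP correlation over CN > 1 edges, strong/weak module
  classification at 0.8.
* **CPM energy.** Constant Potts Model Hamiltonian
  $H = -\sum_c (e_c - \gamma_c n_c^2)$ per partition and per module, with
  per-community $\gamma_c = 1/n_c^2$ (default) or a global resolution;
  energy-heterogeneity checks across tree levels.
* **Synthetic substrates.** Deterministic hierarchical clique-replication
  networks ($b^L$ nodes, $C(k) \sim k^{-1}$, degree exponent near
  $1 + \ln b/\ln(b-1)$), Barabási–Albert and Erdős–Rényi null models, and a
  22-node planted fixture whose module tree and FKR set are known exactly.

Networks are igraph objects; edge-list, SIF and GraphML files are read and
written with `read_network()` / `write_network()`.

## Worked example

```r
library(fkrnet)

## hierarchical substrate: 4^4 = 256 nodes
net <- generate_hierarchical(4, 4)
fit_degree_distribution(igraph::degree(net), n_boot = 250, seed = 1)
#> <power_law_fit> method: mle  exponent: 2.73 (negative)  xmin: 3  KS: 0.134  p: 0
fit_loglog(clustering_by_degree(net)$curve, n_boot = 0)
#> <power_law_fit> method: loglog  exponent: 1.163 (negative)  xmin: 3
```

The degree exponent (2.73) sits near the mean-field hierarchical value
$1 + \ln 4/\ln 3 = 2.26$ and the clustering curve decays almost exactly as
$k^{-1}$ — the two diagnostic scalings of a hierarchical network. The
near-zero bootstrap p-value is a property of this substrate, not of the
fitter: the deterministic construction repeats a handful of degree values
exactly, which a KS test against a smooth power law duly rejects (see the
vignette's limitations section).

```r
## planted fixture with known ground truth
fx   <- planted_fkr_fixture()
tree <- build_module_tree(fx$network)
tree
#> <module_tree> 9 modules over levels 0.. 2 on 22 nodes
#>  level n_modules        q q_per_node
#>      0         1 0.000000 0.00000000
#>      1         4 0.624898 0.02840445
#>      2         4 0.597551 0.02716141

identify_fkr(tree, 10)
#> <fkr_table> 4 fundamental key regulator(s)
#>  gene degree hub_rank terminal_level terminal_module fkr_rank
#>    A1      5        2              2          M0.1.1        1
#>    B1      5        2              2          M0.2.1        1
#>    A4      3        4              2          M0.1.2        2
#>    B2      3        4              2          M0.2.1        2

fkr_probability(tree, "A1")
#>   level module degree module_edges     p_fkr defined
#> 1     0     M0      5           35 0.1428571    TRUE
#> 2     1   M0.1      3            7 0.4285714    TRUE
#> 3     2 M0.1.1      2            3 0.6666667    TRUE
```

Of the top ten hubs, exactly the four planted regulators survive the trace
from the whole network to motif level, and the regulating probability of
`A1` rises monotonically (0.143 → 0.429 → 0.667) as its module shrinks
around it — deeper levels concentrate its influence.

`run_full_analysis(analysis_config(...))` executes all stages from one
seeded configuration and writes per-stage CSV/JSON outputs plus a summary.

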