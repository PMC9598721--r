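---
title: "Sector-averaged LBP retrieval with an evolved Fuzzy ARTMAP: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sector-averaged LBP retrieval with an evolved Fuzzy ARTMAP: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(avnlbp)
library(ggplot2)
```

This vignette is the package's account of the science it implements: the
descriptor, the classifier, the optimizer, the retrieval metrics, the
synthetic data they are exercised on, and the judgement calls made where the
underlying method descriptions leave the design open.

## The problem

Content-based retrieval of grayscale images — the motivating application is
medical image archives (CT, MRI, X-ray) — needs two ingredients: an *index*
(a compact feature vector per image) and a *search mechanism* (a classifier
plus a similarity ranking). Local binary patterns (LBP) are the standard
texture index, but they threshold raw single-pixel differences, so additive
sensor noise flips bits easily and corrupts the histograms. The descriptor at
the core of this package, **AvN-LBP**, replaces single-pixel comparisons with
comparisons of *sector averages* of the neighborhood, trading a little
spatial resolution for substantial noise resistance.

## The AvN-LBP descriptor

Classic LBP at a pixel $x_{0,0}$ samples $p$ neighbors $x_{r,n}$ on a circle
of radius $R$ and accumulates

$$\mathrm{LBP}_{p,R} = \sum_{n=0}^{p-1} S(x_{r,n} - x_{0,0})\, 2^n .$$

AvN-LBP instead partitions the whole $(2R+1)\times(2R+1)$ window (minus the
center) into $p$ angular sectors, averages the intensities of each sector to
get $x'_{r,n}$, and thresholds each sector mean against the grand mean
$\mu_r = \tfrac1p\sum_n x'_{r,n}$:

$$\mathrm{AvN\!-\!LBP}_{p,R} = \sum_{n=0}^{p-1} S(x'_{r,n} - \mu_r)\, 2^n,
\qquad S(x) = \mathbf{1}[x \ge 0].$$

Because the threshold $\mu_r$ is computed from the neighborhood itself,
adding a constant to every pixel changes nothing: the descriptor is exactly
invariant to global illumination shifts (a tested property). Averaging six
pixels per sector before thresholding is what buys the noise robustness: a
zero-mean perturbation must move a whole sector mean past $\mu_r$ to flip a
bit, not a single pixel past the center value.

The per-image feature is the histogram $h(k)$, $k = 0,\dots,2^p-1$, of codes
over all *interior* pixels (those whose window fits inside the image).

```{r fig3}
# the standard worked example: eight sector means -> decimal code
avn_lbp_code(c(160.33, 157.5, 172.66, 157.33, 161.66, 172.66, 192.83, 157.83))
```

### Geometry decisions

Several geometric details are not pinned down by the usual verbal
description of the operator; the package fixes them as follows and documents
them so codes are reproducible:

* **Sector membership is over the square window, not a Euclidean disc.**
  Every offset $(di,dj)$ with $0 < \max(|di|,|dj|) \le R$ is binned by its
  angle (counter-clockwise from the $+x$ axis, rows growing downward) into
  half-open sectors $[n\theta, (n+1)\theta)$. This is the unique simple rule
  for which $R=3,\ p=8$ gives exactly 6 offsets per sector, matching the
  worked example's division by 6; a disc of radius 3 would give unequal
  sector counts.
* **Bit order**: bit $n=0$ is the sector starting at $0^\circ$, increasing
  counter-clockwise. Any fixed order yields an equivalent descriptor (codes
  are a relabeling); one must simply be chosen and kept.
* **Classic-LBP threshold**: the step function is implemented as
  $S(x)=\mathbf{1}[x \ge 1]$ — a strict "greater than center" comparison on
  integer images — with `threshold = 0` available for the conventional
  $\ge$ convention. The AvN-LBP step is $\mathbf{1}[x \ge 0]$; consequently a
  perfectly flat window codes to $2^p - 1$ (every tie counts), a harmless
  deterministic convention.
* **Borders are skipped, never padded**: padding would fabricate intensities
  and bias the histogram, so $\sum_k h(k) = (N-2R)(M-2R)$ exactly.
* **Classic-LBP circle samples** at non-integer positions use bilinear
  interpolation, the standard practice.
* Defaults are $p = 8$, $R = 3$, $\theta = 45^\circ$ throughout. Smaller $p$
  shortens the histogram ($2^p$ bins) at the cost of angular resolution;
  larger $R$ smooths more aggressively.

A documented curiosity of the published worked example: its six printed
sector pixels average to 160.0 (not the printed 160.33) and its eight sector
means average to 166.6 (not the printed 166.26). The final code 100 is
invariant to either reading, so only the code — never the intermediate
values — is used as a fixture.

## The Fuzzy ARTMAP classifier

FAM is an incremental supervised classifier. Features $a \in [0,1]^d$ are
*complement coded* to $AI = (a, 1-a)$, which fixes $|AI|_1 = d$ and bounds
category growth. Each category $j$ stores a weight vector
$W_j \in [0,1]^{2d}$ (a hyperbox) and one class label. For a training
pattern:

1. The first pattern of a new class seeds a category $W = AI$.
2. Otherwise categories compete by the choice function
   $T_j = |AI \wedge W_j|_1 / (\alpha + |W_j|_1)$.
3. The winner must pass the vigilance test
   $|AI \wedge W_J|_1 / |AI|_1 \ge \rho$.
4. If its label matches, it learns
   $W_J \leftarrow \beta (AI \wedge W_J) + (1-\beta) W_J$; if not, *match
   tracking* raises $\rho$ just above the winner's match ratio
   ($+\,\varepsilon$) and the search resumes among the remaining categories.
5. A pattern that exhausts all candidates commits a new category.

Prediction is pure competition: the label of the category with maximal
$T_j$, ties to the lowest index, no vigilance.

Design calls worth stating explicitly:

* **Weight update.** The convex fuzzy-ART update above is the default. A
  purely additive variant ($W + \beta(AI \wedge W)$, clipped) is retained
  behind `update = "printed"` for auditability; unclipped it would leave
  $[0,1]$, so it is not the default.
* **Match tracking scope.** The raised vigilance applies to the current
  pattern only, then resets to the baseline — standard ARTMAP semantics.
* **$\rho = 1$ handling.** A baseline vigilance of exactly 1 would make the
  match test hinge on float equality; it is capped internally at
  $1 - 10^{-9}$, i.e. "vigilance essentially one".
* **$\varepsilon = 0.001$** for the match-tracking increment; any small
  positive value only needs to break the tie against the failed winner.
* **Feature scaling.** Descriptor histograms are divided by their maximum
  count before training, since complement coding needs $[0,1]$ features.
  Max-scaling (rather than sum-scaling) keeps the histogram shape and puts
  the dominant bin at 1 for every image.
* A tuning constant `delta = 0.2` rides along in configurations for
  completeness but is deliberately unbound: it has no defined role in the
  training dynamics.

Training order matters: different presentation orders (and vigilance values)
yield different category counts on overlapping data — *category
proliferation*. The test suite demonstrates this directly, and it is exactly
the diversity the evolutionary step feeds on.

## Evolving the network: DEFAM

A population of $N$ FAM networks is trained with shuffled presentation
orders and vigilance jittered over a range (default $[0.5, 0.9]$, set via
`rho_range` / the `rho_min`/`rho_max` config keys). The jitter range is a
package choice: a population trained at vigilance $\approx 1$ would store
one category per training pattern, exceeding any sensible encoding capacity
and giving the optimizer nothing but infeasible members to work with.

Each network is encoded as a fixed-length real vector: `catmax` slots, each
holding $2d$ weight genes, one label gene, and one validity gene (slot
active iff $\ge 0.5$). Fixed capacity keeps the dimension
$D = \mathrm{catmax}\,(2d+2)$ constant across members, which the vector
arithmetic of differential evolution requires; decoding clips weight genes
to $[0,1]$ and rounds label genes to the nearest class index.

Each generation applies, per member:

* **Mutation** (neighborhood-to-best):
  $V = x_{r3} + F_1 (x_{best} - x_{r3}) + F_2 (x_{r1} - x_{r2})$, with
  $r_1, r_2, r_3$ drawn from the top-ranked fraction (`neigh_frac`,
  default 0.5, valid range 0.3–0.6) of the population and $x_{best}$ the
  global best. Restricting donors to good members speeds convergence; the
  classic strategies (`rand/1`, `best/1`, `rand-to-best/1`, `rand/2`) are
  implemented alongside for comparison.
* **Binomial crossover** with rate `CR` (default 0.7): component $j$ comes
  from the mutant when $\mathrm{rand}_j \le CR$ or $j = j_{rand}$. The
  inverted inequality ($> CR$) occasionally seen in print is available as
  `crossover_dialect = "printed"`; the canonical form is the default
  because 0.7 is quoted as a conventional *crossover rate*.
* **Selection**: the member with the smaller fitness survives; ties keep
  the target, so the best fitness is non-increasing by construction.

### The fitness and its repair

The objective couples accuracy `pcc` (percent correct on an evaluation set)
with the active category count `Na`, given user bounds
$\mathrm{catmin} \le \mathrm{catmax}$ (a good `catmin` equals the number of
classes). The intended optimum is the smallest feasible network at full
accuracy: $Na = \mathrm{catmin}$, $pcc = 100$. The printed form of this
objective,

$$F(p) = \frac{100\,\mathrm{catmin} - pcc \cdot Na}{(\mathrm{catmax} - Na)\,
pcc^2},$$

is signed and diverges as $Na \to \mathrm{catmax}$, so some repair is
unavoidable. Taking the absolute numerator and minimizing is the obvious
first step, but it leaves a genuine defect that implementation exposed:
$|100\,\mathrm{catmin} - pcc \cdot Na| = 0$ along the whole hyperbola
$pcc \cdot Na = 100\,\mathrm{catmin}$, which contains low-accuracy networks
(e.g. $pcc = 33.3\%$, $Na = 9$ at $\mathrm{catmin} = 3$), and since $pcc$ is
a rational number with the evaluation-set size as denominator, the zero is
*exactly attainable* — a test run converged to precisely such a garbage
network. The default numerator therefore adds an accuracy-deficit term:

$$\text{numerator} = |100\,\mathrm{catmin} - pcc \cdot Na| +
\mathrm{catmin}\,(100 - pcc),$$

whose only zero is the intended optimum. The bare absolute form remains
available as `fitness_form = "guarded"`, and the raw printed ratio as
`defam_fitness_raw()`, for inspection. Members outside
$\mathrm{catmin} \le Na < \mathrm{catmax}$ (the upper bound is open because
the denominator vanishes at $Na = \mathrm{catmax}$) or with $pcc = 0$
receive a large finite penalty plus their distance to the feasible band, so
infeasible members are still ranked usefully rather than discarded.

```{r evolve}
# overlapping two-dimensional clusters provoke category proliferation
set.seed(42)
x <- pmin(pmax(rbind(matrix(rnorm(80, 0.35, 0.15), 40, 2),
                     matrix(rnorm(80, 0.65, 0.15), 40, 2)), 0), 1)
y <- rep(c("a", "b"), each = 40)
nets <- fam_population(x, y, n = 8, params = fam_params(rho = 0.8, epochs = 1),
                       rho_range = c(0.6, 0.9), seed = 1)
range(vapply(nets, n_categories, 1L))
fit <- defam_evolve(nets, x, y,
                    de_params(catmin = 2, catmax = 40, generations = 25, seed = 2))
glance(fit)
```

```{r trace-plot, fig.width = 5, fig.height = 3}
autoplot(fit)
```

## Retrieval and its metrics

The database holds one histogram per image; queries are ranked by ascending
L1 distance between max-normalized histograms ($\chi^2$ available via
`distance = "chisq"`). The similarity measure is a package choice — L1 on
normalized histograms is the common default in LBP retrieval work. With a
classifier, retrieval is *classify-then-search*: entries of the predicted
class are ranked ahead of the rest, each block sorted by distance. Both
modes exist because descriptor-only and classifier-guided retrieval are both
legitimate operating points; pure-distance mode is also what the
noise-robustness comparison uses so that only the descriptor differs.

Scoring per query $I_q$ with relevance = same class:

$$P(I_q) = \frac{|N_R \cap N_{RT}|}{n_{RT}}, \qquad
R(I_q) = \frac{|N_R \cap N_{RT}|}{n_R},$$

ARP is the mean precision at a fixed depth (default 10) and ARR the mean
recall at depth $\max(n_R, 10)$; both depths are configurable
(`k_precision`, `k_recall_min`) since evaluation protocols vary (e.g. top-25
is common for class-level accuracy).

## Synthetic textures

The generator exists so every stage is testable without any external image
archive. It emulates the one property the pipeline actually relies on:
*classes that differ in second-order spatial statistics*. Two families:

* **Sinusoidal gratings** — class parameters orientation and spatial
  frequency; per-image random phase and a small ($\sigma = 1.5^\circ$)
  orientation jitter make images within a class distinct. Default
  frequency 0.125 cycles/pixel (an 8-pixel period) is matched to the
  default 7-pixel descriptor window.
* **Gaussian random fields** — white noise smoothed by a Gaussian kernel
  with class-specific correlation length, standardized to mean 127, sd 40.

Optional additive Gaussian noise is calibrated by SNR in dB
($10\log_{10}$ of the signal/noise variance ratio, computed on the image's
empirical variance). Splits are stratified 40/30/30
(train/test/validation) by default, sized by the largest-remainder rule with
ties to the earlier split.

What the generator does *not* emulate: anatomical content, intensity
calibration differences between scanners, within-class structural variation
beyond phase/realization noise, or class imbalance (unless configured).
Passing tests on these textures show the machinery is correct and that
sector averaging beats pixel thresholding under additive noise *in this
controlled family*; they are not evidence about any particular clinical
archive.

## Problem sizes and numerical choices in the test suite

The shipped tests and the acceptance script use deliberately small,
seed-fixed instances, chosen as the smallest sizes at which each property is
informative: $64\times64$ images, 3–6 classes with 8–10 images per class for
descriptor/retrieval checks (noise trend: 6 classes, SNR 30/20/10 dB, five
seeds); 2–4-dimensional cluster sets of 45–90 points for classifier and
evolution checks (population $N = 8$, 30–40 generations). Oracle
equivalence is checked against independent straight-line reimplementations
(per-pixel double loops for the descriptors, a plain-loop training pass for
the classifier) on instances small enough to trust by inspection.

Other numerics: tie-breaks are always "lowest index wins" (category choice,
ranking, selection); sector binning adds $10^{-9}$ degrees before flooring
to absorb float fuzz at exact bin boundaries; circle offsets are rounded at
the ninth decimal so axis-aligned samples land on integer pixels; the
stagnation guard in `defam_evolve()` (off by default) returns the best
member so far with a warning rather than failing.

## Known limitations

* FAM categories grow linearly with data under high vigilance; the
  evolutionary step controls the final network but training-time cost of the
  initial population is unchanged.
* The slot encoding fixes capacity at `catmax`; a network that legitimately
  needs more categories cannot be represented and encoding fails loudly.
* ARR at depths below the class size is bounded away from 1 by
  construction; compare protocols before comparing numbers.
* The descriptor is not rotation invariant (by design — orientation is
  discriminative for textures); rotation-invariant code mappings are out of
  scope.
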