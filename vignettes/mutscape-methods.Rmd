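---
title: "Changing environments and the local mutational landscape: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Changing environments and the local mutational landscape: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

mutscape is a desk-scale digital-evolution system for studying how
cyclically changing environments reshape the *local mutational landscape*
of evolving organisms: the fitness and phenotype structure of every
genome reachable by a single substitution. Populations of
self-replicating programs evolve on a toroidal grid under static or
fluctuating reward schedules; the package then measures their ancestry
(phylogenetic depth, most recent common ancestor, selective sweeps),
their diversity (per-site Shannon entropy), their genetic architecture
(functional and vestigial sites), and their one- and two-step mutational
neighborhoods, summarized as genomic and phenotypic diffusion rates.

This vignette records the model, its assumptions, the tunable parameters
and their defaults, the numerical choices, and the design decisions made
where the design was genuinely open.

## The substrate

An organism is a fixed-length genome over a 26-symbol instruction
alphabet (serialized as letters a--z), executed by a deterministic
virtual CPU with three 32-bit registers (AX, BX, CX), a small stack
(depth 16), and a cycling input cursor. One update of execution runs one
instruction; by default a genome is evaluated with a step budget equal
to its length, i.e. a single pass from the serialization origin (the
genome is logically circular, so larger budgets wrap). Execution
therefore always halts within the budget, and a malformed program simply
emits nothing.

Designated roles: `a` is the inert instruction used as knockout filler
(`b`, `c`, `z` are also inert), `d` loads the next evaluation input into
BX, `e` emits BX as an output, `y` marks replication, and `l` is NAND --
together with the io instructions it suffices to express every logic
task. The remaining instructions are register moves, bitwise logic,
shifts, arithmetic and stack operations (`instruction_set()` lists all
26). Because the alphabet has exactly 26 symbols, every site has exactly
25 alternative symbols under substitution, so a length-121 genome has a
one-step neighborhood of 3,025 distinct mutants.

An organism is *viable* iff the replication instruction executes within
the budget; a non-viable organism performs no tasks by definition and
has zero merit. This is a deliberately reduced substrate: there is no
self-copying loop, no flow control, and genome length never changes (no
insertions or deletions). All downstream metrics depend only on the
genotype-to-(phenotype, fitness) map.

## Tasks and detection

Phenotype is the set of bitwise logic tasks an organism performs. The
catalog (`logic_tasks(3)`) contains every boolean function of 1--3
inputs, deduplicated under permutation of the inputs, excluding the two
constants and the single-input identity (echo): 1 one-input task (NOT),
8 more at two inputs (the classic logic-9), and 68 more at three inputs,
for 77 tasks in total ("Logic-77"). XOR and EQU form the *basic* set --
the constantly rewarded backbone task and the fluctuating task; the
other 75 are the *expanded* set. The canonical representative of each
task is the lexicographically smallest truth table over input
permutations; the unit suite checks the whole catalog against a
brute-force enumerator of all $2^{2^k}$ functions.

Every experiment evaluates organisms against one fixed triple of 32-bit
input words, drawn once from the experiment seed. A task is credited iff
some emitted output equals the task applied bitwise to some ordered
selection of distinct inputs; each task is credited at most once per
organism. A triple is accepted only if its 32 bit-columns cover all 8
three-bit input patterns (about 89% of random triples). This condition
is sufficient for exact detection: two distinct boolean functions of the
three words must then differ in at least one bit position, so no two
catalog tasks -- and no task and a plain echoed input -- can ever
produce the same output word. Detection by word equality is thus
provably collision-free, not merely improbable to collide.

A representational note: machine words are held as doubles in
$[0, 2^{32})$ at the R level. R's integer type cannot represent the bit
pattern `0x80000000` (it is the NA sentinel), and task target words do
occasionally take exactly that value; doubles are exact for all 32-bit
values and convert losslessly at the C++ boundary.

## Reward schedules and merit

Merit (fitness) is multiplicative with base 1: the product of the
multipliers of the tasks performed, or 0 if non-viable. Under the static
control, XOR earns $2^3 = 8$ and EQU $2^5 = 32$, constantly. In the
cyclic treatments a phase lasts `cycle_length` updates (reward first)
and EQU alternates between the $2^5$ reward and: no reward ($2^0$) in
the *benign* treatment, or a $2^5$-fold penalty ($2^{-5}$) in the
*harsh* treatment. In stage 2 each expanded task earns a constant
1.2-fold bonus; the *quiescent* variants additionally stop the
fluctuation at the stage-2 boundary and reward the basic set constantly.
The bonus is taken as exactly 1.2 ("a constant 1.2-fold bonus") rather
than $2^{0.3} \approx 1.231$; both the schedule table and this choice
are configurable.

Expected fitness across environments is the probability-weighted sum
$E(w) = \sum_i w_i P_i$ (`expected_fitness()`), used to aggregate
mutational surveys over the phases of a fluctuating schedule.

## Population dynamics

Populations live on a W x H toroidal grid (default desk scale 20 x 20;
full scale 60 x 60 = 3,600 cells), seeded with a single ancestor that
performs XOR and EQU at the grid center. Each update every organism
accrues reproductive energy; an organism whose energy reaches the
gestation cost reproduces: the offspring genome receives independent
per-site substitutions with probability $\mu$ (uniform over the 25
alternative symbols), is placed in a uniformly random cell of the
parent's 8-cell Moore neighborhood, replacing any occupant, and both
parent and child energies reset to zero. Cells act in fixed scan order
(the deterministic tie-break for simultaneous births) and newborns act
from the next update. Replacement-only dynamics keep the population at
most W x H forever.

Two energy schedulers are provided. The *absolute* scheduler adds merit
itself each update, so reproduction rate is directly proportional to
merit; it is the simplest reading of merit-as-CPU-speed and is the
default for `make_world()`/`step_update()`, whose unit contracts (first
birth at `ceiling(cost / fitness)` updates) assume it. Experiments
(`run_experiment()`) default to the *relative* scheduler, which adds
merit divided by the population's current mean merit -- the
merit-proportional CPU allocation used by established digital-evolution
platforms. The distinction matters for cross-treatment comparisons:
under absolute accrual a static population at merit 256 turns over 32
times faster in wall-clock updates than a punished harsh population, so
ancestry depth and diversity comparisons would measure reward scale
rather than evolutionary dynamics. Under the relative scheduler an
average-merit organism reproduces every `cost` updates (default 10 at
desk scale, about 20 generations per phase) regardless of the absolute
reward level.

## Desk-scale study conditions

The full-scale design is a 60 x 60 grid, genome length 121,
$\mu = 0.00075$ per site, 1,000-update phases and 200 phases per stage.
The desk preset used by the default `experiment_config()` scales this to
a 20 x 20 grid, genome length 60, 200-update phases -- and keeps the
full design's 200 phases per stage, because the number of environmental
reversals is the defining feature of the cyclic treatments and the
architectural signal accumulates over them. Two further desk choices:

* `mu = 0.003`, four times the full-scale rate. With a 9-fold smaller
  population and 5-fold shorter phases, the full-scale mutation rate
  would starve the per-phase mutational supply that loss-and-regain
  dynamics depend on; a 4x rate keeps that supply within a small factor
  of the full-scale study's while leaving the genomic rate per
  replication (0.18) far below one.
* gestation `cost = 10` updates under the relative scheduler, giving
  roughly 20 generations per phase, the same order as the full design
  (about 30 generations per 1,000-update phase).

With these conditions a single stage-1 run is 40,000 updates and takes
a couple of seconds; the directional comparison suite (3 treatments x
10 replicates) runs in a few minutes.

## Landscape metrics

The exhaustive one-step survey (`one_step_survey()`) enumerates all
$l \times 25$ single-site substitutions and classifies each mutant
against its parent. With per-site mutation probability $\mu$ and genome
length $l$:

* fidelity $F = (1-\mu)^l$, the probability an offspring is
  genotypically identical to its parent;
* $p_d$, the fraction of one-step mutants that are detrimental or
  lethal, and $p_\nu = 1 - p_d$ the neutral-or-beneficial fraction;
* neutral fidelity $F_\nu = (1-\mu p_d)^l$, the probability that no
  harmful mutation occurs (assuming no epistasis across sites);
* the genomic diffusion rate $D_g = F_\nu - F$, the probability of a
  genotypically distinct yet fitness-neutral-or-better offspring;
* $p_{p\nu}$, the phenotype-preserving fraction;
  $\mu_{pheno} = \mu (1 - p_{p\nu})$;
  $F_{p\nu} = (1-\mu_{pheno})^l$; and the phenotypic diffusion rate
  $D_p = F_\nu - F_{p\nu}$, the probability of a neutral-or-better
  offspring with a *different* phenotype.

Numerical conventions. "Neutral or better" means mutant fitness
$\ge$ parent fitness $\times (1-\varepsilon)$ with
$\varepsilon = 10^{-9}$; merit products of power-of-two bonuses are
exactly representable, so $\varepsilon$ only guards float noise.
$p_{p\nu}$ is, by default, the fraction of mutants that are *both*
phenotype-identical *and* neutral-or-better (the "subset" convention),
which guarantees $p_{p\nu} \le p_\nu$ and hence $D_p \ge 0$; the
literal reading (phenotype-identical regardless of fitness) is
available via `ppnu = "literal"`. Both fractions are reported on every
survey.

Survey context. For fluctuating treatments a mutant's fitness depends
on the phase, so surveys default to expected-fitness aggregation over
both stage-1 phases at $P = (1/2, 1/2)$; a single-phase context
(`survey_context(mode = "phase")`) is also provided, and
`aggregate_across_environments()` recombines single-environment surveys
under any $P$. Which convention the original full-scale analysis used
is not stated; both are implemented.

The two-step regain survey takes every one-step mutant that lost a
focal task and enumerates its single-site substitutions *excluding any
change at the originally mutated site* (one additional, non-reversion
mutation), reporting the fraction that perform the task again. Cost
control: exhaustive below a configurable evaluation budget (default
$10^6$), else uniform sampling under the run's seed. A parallel
sampling survey (`sampled_multimutation_survey()`) draws offspring
through the mutation model itself, allowing multiple simultaneous hits;
its $p_d$ estimate converges to the exhaustive single-step value as
$\mu \to 0$.

## Ancestry, sweeps and vestigial sites

The phylogeny records every genotype-changing birth (an offspring
identical to its parent shares its parent's node). Phylogenetic depth
counts genotype-changing births from the ancestor. The MRCA of the
living population is sampled at a fixed interval; a *sweep* is a change
of MRCA identity between consecutive samples, so the sweep count of a
run is the number of such changes.

Site classification knocks out each site in turn (replacement by the
inert instruction) and labels it by consequence: replication-critical,
functional for the task set it loses, or none. A site is *vestigial*
for task T iff at some sampled ancestor at or after the site's last
mutation the site was functional for T, and it is not currently
functional for T -- unchanged since it previously coded for a function
that a mutation elsewhere disabled. Functional and vestigial labels for
the same task are mutually exclusive per site. Ancestor classification
walks the line of descent of the focal organism; at desk scale every
ancestor can be classified, with configurable thinning for longer
lineages (the treatment pipeline thins to at most 100 ancestors).

## Diversity, discovery and performance

Per-site diversity is the Shannon entropy (base 2) of the symbol
frequencies at each site, between 0 and $\log_2 26 \approx 4.70$ bits;
population diversity is the mean over sites. A task is *non-ephemeral*
at a sampling point when performed by strictly more than 0.1% of the
population capacity -- the smallest qualifying count at the full-scale
capacity of 3,600 is 4 performers, which fixes the rounding rule
(`floor(threshold * capacity) + 1`, at least 1). Task discovery is the
monotone union of non-ephemeral tasks over samples (counted from the
experiment start, and separately from the stage-2 boundary); task
performance is the number of currently non-ephemeral tasks, never
exceeding the discovered count.

## Statistical procedures

Treatment comparisons use the Kruskal-Wallis test across groups and
pairwise Wilcoxon rank-sum tests with a tie-corrected
normal-approximation Z (no continuity correction; the variant used in
the original analysis is unstated), Bonferroni-adjusted over the number
of pairwise comparisons. Associations use Spearman's rank correlation.
Task-loss and task-regain architecture relationships use ordinary least
squares with one or two predictors (loss fraction on functional site
count; regain fraction on functional and vestigial site counts). These
procedures are validated by simulation in the test suite: rejection
rates under 3-SD shifts, false-positive rates under the null, and
slope-recovery coverage at known effect sizes.

## Synthetic fixtures and their ground truth

Every pipeline stage is testable without running evolution:

* `make_task_genome()` compiles any requested task set into a genome,
  each task as an irredundant prime-implicant cover (sum of products)
  whose terms open with rewind/zero prologues so that register and
  input-cursor state never couples one term's knockout to another. The
  returned per-site map (functional for which task, replication,
  inert) is computed by an independent *symbolic* executor that runs
  the program over 8-row truth tables instead of concrete words --
  under the input-coverage guarantee, word equality coincides with
  truth-table equality, so the symbolic knockouts decide functionality
  exactly. At construction the map is verified against the concrete
  `classify_sites()`; all 77 tasks compile and verify. Vestigial
  motifs are built as complete task segments whose emit instruction is
  replaced by the inert symbol; restoring the identified disabling
  site restores the task.
* `make_lineage_fixture()` builds a birth chain with a prescribed
  phylogenetic depth and an MRCA series with a prescribed sweep count.
* `make_population_fixture()` expands exact genotype counts into a
  population whose per-site entropies are computed directly from the
  frequency specification.
* `make_survey_stub()` realizes requested $p_d$ and $p_{p\nu}$
  fractions exactly (up to floor rounding) over a one-step
  neighborhood, isolating the diffusion equations from the substrate.

What the generator emulates -- and does not. The synthetic runs emulate
the study's selective structure: multiplicative task rewards, cyclic
reversals, spatial replacement, substitution-only mutation at fixed
genome length. They do not emulate a flow-control-rich CPU (no loops or
jumps), self-copying replication, insertion/deletion mutation, or
resource-limited rewards. Passing tests therefore certify the metric
definitions and the directional ecology of the model, not bit-level
agreement with any particular full-scale platform.

## Known limitations

* **Task-length growth does not emerge.** In the full-scale study,
  repeated loss and regain of the fluctuating task lengthened its
  genomic footprint, and longer tasks lost more mutants; regain there
  often proceeded through new mutational paths. In this substrate,
  regain is dominated by exact reversion of the disabling site, so
  fluctuating treatments evolve *compact toggle* architectures instead:
  the EQU-only site count rises and the XOR/EQU overlap shrinks (the
  architectural separation the full-scale study also reports), but the
  total EQU footprint does not grow. Consequently the desk-scale
  fraction of EQU-losing one-step mutants does not exceed the static
  control's, unlike at full scale.
* **Benign fluctuation is weak at desk scale.** With the off-phase
  merely removing the EQU reward, a 20-generation phase is too short
  for drift to move the dominant genotype; benign populations remain
  statistically indistinguishable from static controls in the
  neighborhood measures. The harsh treatment, whose off-phase actively
  punishes, shows the full qualitative pattern: collapse and recovery
  of EQU performance within cycles, elevated sweep counts and
  phylogenetic depth, reduced diversity, and an elevated phenotypic
  diffusion rate driven by reactivation paths through disabled (vestigial)
  task material.
* **Survey object under cyclic schedules.** Harsh runs end at the end
  of a punishment phase, where the fluctuating task is absent by
  construction. Landscape metrics are therefore taken on the
  end-of-experiment dominant (the study's stated object), while the
  EQU-loss fraction -- defined only for an EQU-performing parent -- is
  taken on the most abundant EQU-performing genotype of the final
  population, falling back to the dominant at the end of the last
  rewarded phase.
* Printed full-scale inferential statistics (Z scores, $R^2$ values,
  sweep-count means) required 150 runs of 400,000 updates on the
  original platform and are not reproduced numerically; the package
  validates the procedures and the directions of the contrasts.
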