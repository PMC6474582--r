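// Virtual CPU, mutational-neighborhood scans, and the toroidal-grid
// population update loop. Words are 32-bit (uint32_t internally; doubles in
// [0, 2^32) at the R interface). Genomes are integer code vectors 0..25 (letters a-z).
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

// instruction opcodes (letter index 0..25)
enum {
  OP_NOPA = 0, OP_NOPB = 1, OP_NOPC = 2,
  OP_LOAD = 3,  // d: BX <- next input (cycling)
  OP_EMIT = 4,  // e: emit BX
  OP_SWAP = 5,  // f: swap BX, CX
  OP_MOVC = 6,  // g: CX <- BX
  OP_MOVA = 7,  // h: AX <- BX
  OP_MOVB = 8,  // i: BX <- AX
  OP_PUSH = 9,  // j
  OP_POP = 10,  // k (empty stack -> 0)
  OP_NAND = 11, OP_AND = 12, OP_OR = 13, OP_XOR = 14, OP_NOT = 15,
  OP_SHL = 16, OP_SHR = 17,
  OP_REWIND = 18, // s: reset input cursor
  OP_INC = 19,
  OP_ZERO = 20, OP_ONES = 21,
  OP_ADD = 22, OP_SUB = 23,
  OP_REPRO = 24,
  OP_NOPZ = 25
};

static const int STACK_MAX = 16;

struct VMResult {
  std::vector<uint32_t> outputs;
  bool replicated;
};

static void vm_run(const uint8_t *g, int l, const uint32_t *inputs,
                   int n_inputs, int max_steps, VMResult &res) {
  uint32_t ax = 0, bx = 0, cx = 0;
  uint32_t stack[STACK_MAX];
  int sp = 0, pos = 0, ip = 0;
  res.outputs.clear();
  res.replicated = false;
  if (l <= 0) return;
  for (int step = 0; step < max_steps; ++step) {
    switch (g[ip]) {
    case OP_LOAD:
      if (n_inputs > 0) { bx = inputs[pos]; pos = (pos + 1) % n_inputs; }
      break;
    case OP_EMIT: res.outputs.push_back(bx); break;
    case OP_SWAP: { uint32_t t = bx; bx = cx; cx = t; } break;
    case OP_MOVC: cx = bx; break;
    case OP_MOVA: ax = bx; break;
    case OP_MOVB: bx = ax; break;
    case OP_PUSH: if (sp < STACK_MAX) stack[sp++] = bx; break;
    case OP_POP: bx = (sp > 0) ? stack[--sp] : 0u; break;
    case OP_NAND: bx = ~(bx & cx); break;
    case OP_AND: bx = bx & cx; break;
    case OP_OR: bx = bx | cx; break;
    case OP_XOR: bx = bx ^ cx; break;
    case OP_NOT: bx = ~bx; break;
    case OP_SHL: bx = bx << 1; break;
    case OP_SHR: bx = bx >> 1; break;
    case OP_REWIND: pos = 0; break;
    case OP_INC: bx = bx + 1u; break;
    case OP_ZERO: bx = 0u; break;
    case OP_ONES: bx = ~0u; break;
    case OP_ADD: bx = bx + cx; break;
    case OP_SUB: bx = bx - cx; break;
    case OP_REPRO: res.replicated = true; break;
    default: break; // nops
    }
    ip = (ip + 1) % l;
  }
}

// word -> task lookup built from parallel sorted arrays
struct TargetTable {
  std::vector<uint32_t> words; // sorted
  std::vector<int> task;       // 0-based task index, parallel to words
  int n_tasks;
};

static void lookup_tasks(const TargetTable &tt, uint32_t w,
                         std::vector<uint8_t> &mask) {
  size_t lo = 0, hi = tt.words.size();
  while (lo < hi) {
    size_t mid = (lo + hi) / 2;
    if (tt.words[mid] < w) lo = mid + 1; else hi = mid;
  }
  while (lo < tt.words.size() && tt.words[lo] == w) {
    mask[tt.task[lo]] = 1;
    ++lo;
  }
}

// phenotype = (viable, task mask); non-viable organisms perform no tasks
static bool phenotype_of(const uint8_t *g, int l, const uint32_t *inputs,
                         int n_inputs, int max_steps, const TargetTable &tt,
                         std::vector<uint8_t> &mask) {
  VMResult res;
  vm_run(g, l, inputs, n_inputs, max_steps, res);
  std::fill(mask.begin(), mask.end(), 0);
  if (!res.replicated) return false;
  for (size_t i = 0; i < res.outputs.size(); ++i)
    lookup_tasks(tt, res.outputs[i], mask);
  return true;
}

static TargetTable make_targets(NumericVector sorted_words,
                                IntegerVector word_task0, int n_tasks) {
  TargetTable tt;
  tt.n_tasks = n_tasks;
  tt.words.resize(sorted_words.size());
  tt.task.resize(sorted_words.size());
  for (int i = 0; i < sorted_words.size(); ++i) {
    tt.words[i] = (uint32_t)sorted_words[i];
    tt.task[i] = word_task0[i];
  }
  return tt;
}

static std::vector<uint32_t> as_words(NumericVector x) {
  // words arrive as doubles in [0, 2^32)
  std::vector<uint32_t> w(x.size());
  for (int i = 0; i < x.size(); ++i) w[i] = (uint32_t)x[i];
  return w;
}

static std::vector<uint8_t> as_codes(IntegerVector g) {
  std::vector<uint8_t> v(g.size());
  for (int i = 0; i < g.size(); ++i) v[i] = (uint8_t)g[i];
  return v;
}

// [[Rcpp::export]]
List cpp_execute(IntegerVector genome, NumericVector inputs, int max_steps) {
  std::vector<uint8_t> g = as_codes(genome);
  std::vector<uint32_t> in = as_words(inputs);
  VMResult res;
  vm_run(g.data(), g.size(), in.data(), in.size(), max_steps, res);
  NumericVector out(res.outputs.size());
  for (size_t i = 0; i < res.outputs.size(); ++i)
    out[i] = (double)res.outputs[i];
  return List::create(_["outputs"] = out,
                      _["replicated"] = res.replicated);
}

// [[Rcpp::export]]
List cpp_phenotype(IntegerVector genome, NumericVector inputs, int max_steps,
                   NumericVector sorted_words, IntegerVector word_task0,
                   int n_tasks) {
  TargetTable tt = make_targets(sorted_words, word_task0, n_tasks);
  std::vector<uint8_t> g = as_codes(genome);
  std::vector<uint32_t> in = as_words(inputs);
  std::vector<uint8_t> mask(n_tasks);
  bool viable = phenotype_of(g.data(), g.size(), in.data(), in.size(),
                             max_steps, tt, mask);
  LogicalVector m(n_tasks);
  for (int i = 0; i < n_tasks; ++i) m[i] = mask[i] != 0;
  return List::create(_["viable"] = viable, _["tasks"] = m);
}

// Exhaustive one-step scan: for every site and every alternative symbol,
// the mutant's viability and task mask. Mutants are ordered site-major,
// symbols ascending with the parental symbol skipped.
// [[Rcpp::export]]
List cpp_survey_masks(IntegerVector genome, int n_symbols,
                      NumericVector inputs, int max_steps,
                      NumericVector sorted_words, IntegerVector word_task0,
                      int n_tasks) {
  TargetTable tt = make_targets(sorted_words, word_task0, n_tasks);
  std::vector<uint8_t> g = as_codes(genome);
  std::vector<uint32_t> in = as_words(inputs);
  int l = g.size();
  int n_mut = l * (n_symbols - 1);
  IntegerVector site(n_mut), symbol(n_mut);
  LogicalVector viable(n_mut);
  LogicalMatrix masks(n_mut, n_tasks);
  std::vector<uint8_t> mask(n_tasks);
  int idx = 0;
  for (int s = 0; s < l; ++s) {
    uint8_t orig = g[s];
    for (int a = 0; a < n_symbols; ++a) {
      if (a == (int)orig) continue;
      g[s] = (uint8_t)a;
      bool v = phenotype_of(g.data(), l, in.data(), in.size(), max_steps,
                            tt, mask);
      site[idx] = s + 1; // 1-based for R
      symbol[idx] = a;
      viable[idx] = v;
      for (int t = 0; t < n_tasks; ++t) masks(idx, t) = mask[t] != 0;
      ++idx;
    }
    g[s] = orig;
  }
  return List::create(_["site"] = site, _["symbol"] = symbol,
                      _["viable"] = viable, _["tasks"] = masks);
}

// Knockout scan: replace each site in turn by the inert symbol.
// [[Rcpp::export]]
List cpp_knockout_masks(IntegerVector genome, int inert,
                        NumericVector inputs, int max_steps,
                        NumericVector sorted_words, IntegerVector word_task0,
                        int n_tasks) {
  TargetTable tt = make_targets(sorted_words, word_task0, n_tasks);
  std::vector<uint8_t> g = as_codes(genome);
  std::vector<uint32_t> in = as_words(inputs);
  int l = g.size();
  LogicalVector viable(l);
  LogicalMatrix masks(l, n_tasks);
  std::vector<uint8_t> mask(n_tasks);
  for (int s = 0; s < l; ++s) {
    uint8_t orig = g[s];
    g[s] = (uint8_t)inert;
    bool v = phenotype_of(g.data(), l, in.data(), in.size(), max_steps, tt,
                          mask);
    viable[s] = v;
    for (int t = 0; t < n_tasks; ++t) masks(s, t) = mask[t] != 0;
    g[s] = orig;
  }
  return List::create(_["viable"] = viable, _["tasks"] = masks);
}

// Two-step regain scan. For each first-step mutant (site/symbol pairs,
// 1-based sites), enumerate or sample single-site substitutions at every
// site other than the originally mutated one, and count how many of these
// non-reversion second-step mutants perform the focal task.
// budget <= 0 means exhaustive; otherwise `budget` uniform draws per
// first-step mutant (R RNG).
// [[Rcpp::export]]
List cpp_two_step(IntegerVector genome, int n_symbols,
                  IntegerVector first_site, IntegerVector first_symbol,
                  NumericVector inputs, int max_steps,
                  NumericVector sorted_words, IntegerVector word_task0,
                  int n_tasks, int focal_task0, int budget) {
  TargetTable tt = make_targets(sorted_words, word_task0, n_tasks);
  std::vector<uint8_t> base = as_codes(genome);
  std::vector<uint32_t> in = as_words(inputs);
  int l = base.size();
  int nf = first_site.size();
  IntegerVector n_tested(nf), n_regain(nf);
  std::vector<uint8_t> mask(n_tasks);
  RNGScope scope;
  for (int i = 0; i < nf; ++i) {
    std::vector<uint8_t> g = base;
    int s1 = first_site[i] - 1;
    g[s1] = (uint8_t)first_symbol[i];
    int tested = 0, regain = 0;
    if (budget <= 0) {
      for (int s = 0; s < l; ++s) {
        if (s == s1) continue;
        uint8_t orig = g[s];
        for (int a = 0; a < n_symbols; ++a) {
          if (a == (int)orig) continue;
          g[s] = (uint8_t)a;
          bool v = phenotype_of(g.data(), l, in.data(), in.size(),
                                max_steps, tt, mask);
          ++tested;
          if (v && mask[focal_task0]) ++regain;
        }
        g[s] = orig;
      }
    } else {
      for (int b = 0; b < budget; ++b) {
        int s;
        do { s = (int)(unif_rand() * l); if (s >= l) s = l - 1; }
        while (s == s1);
        uint8_t orig = g[s];
        int a = (int)(unif_rand() * (n_symbols - 1));
        if (a >= (int)orig) ++a;
        g[s] = (uint8_t)a;
        bool v = phenotype_of(g.data(), l, in.data(), in.size(), max_steps,
                              tt, mask);
        ++tested;
        if (v && mask[focal_task0]) ++regain;
        g[s] = orig;
      }
    }
    n_tested[i] = tested;
    n_regain[i] = regain;
  }
  return List::create(_["n_tested"] = n_tested, _["n_regain"] = n_regain);
}

// ---------------------------------------------------------------------------
// Population dynamics on a toroidal W x H grid with Moore-neighborhood
// replacement. Organisms accrue energy equal to their merit each update and
// reproduce (energy resets to 0) once energy >= cost. Offspring genomes
// receive independent per-site substitutions with probability mu, uniform
// over the 25 non-parental symbols. Cells are processed in fixed scan order;
// newborns do not act until the next update. All randomness via the R RNG.

struct Genotype {
  std::string genome;
  bool viable;
  std::vector<uint8_t> mask;
  double merit[4]; // stage/phase rows
};

// [[Rcpp::export]]
List cpp_run_evolution(IntegerVector init_cells, List init_genomes,
                       int W, int H, double mu, double cost,
                       int n_updates, int start_update,
                       NumericMatrix multipliers, // 4 x n_tasks
                       int cycle_length, int stage2_start,
                       NumericVector inputs, int max_steps,
                       NumericVector sorted_words, IntegerVector word_task0,
                       int n_tasks, int n_symbols,
                       int sampling_interval,
                       NumericVector init_energy,
                       bool relative_scheduler) {
  TargetTable tt = make_targets(sorted_words, word_task0, n_tasks);
  std::vector<uint32_t> in = as_words(inputs);
  RNGScope scope;

  int N = W * H;
  std::vector<int> grid(N, -1);     // genotype index per cell
  std::vector<int> node(N, -1);     // phylogeny node per cell
  std::vector<double> energy(N, 0.0);
  std::vector<int> born_at(N, -1);

  std::vector<Genotype> gts;
  std::unordered_map<std::string, int> gt_index;

  // phylogeny arrays (every node is a genotype-changing birth or a founder)
  std::vector<int> ph_parent, ph_update, ph_depth, ph_gt;
  std::vector<int> ph_moff; // offset into mutation arrays (size = n_nodes+1)
  std::vector<int> mut_site, mut_sym;
  ph_moff.push_back(0);

  int l = 0;
  {
    // founders: init_genomes[i] placed at cell init_cells[i] (1-based)
    for (int i = 0; i < init_cells.size(); ++i) {
      IntegerVector gi = init_genomes[i];
      l = gi.size();
      std::string key((size_t)l, '\0');
      for (int j = 0; j < l; ++j) key[j] = (char)gi[j];
      int id;
      std::unordered_map<std::string, int>::iterator it = gt_index.find(key);
      if (it == gt_index.end()) {
        Genotype G;
        G.genome = key;
        G.mask.resize(n_tasks);
        G.viable = phenotype_of((const uint8_t *)key.data(), l, in.data(),
                                in.size(), max_steps, tt, G.mask);
        for (int r = 0; r < 4; ++r) {
          double m = G.viable ? 1.0 : 0.0;
          if (G.viable)
            for (int t = 0; t < n_tasks; ++t)
              if (G.mask[t]) m *= multipliers(r, t);
          G.merit[r] = m;
        }
        id = (int)gts.size();
        gts.push_back(G);
        gt_index[key] = id;
      } else id = it->second;
      int cell = init_cells[i] - 1;
      grid[cell] = id;
      energy[cell] = (init_energy.size() > i) ? init_energy[i] : 0.0;
      // one founder node per distinct initial cell
      int nd = (int)ph_parent.size();
      ph_parent.push_back(-1);
      ph_update.push_back(start_update - 1);
      ph_depth.push_back(0);
      ph_gt.push_back(id);
      ph_moff.push_back((int)mut_site.size());
      node[cell] = nd;
    }
  }

  static const int DX[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int DY[8] = {-1, -1, -1, 0, 0, 1, 1, 1};

  int n_samples = n_updates / sampling_interval;
  if (n_updates % sampling_interval != 0) ++n_samples;
  IntegerVector s_update(n_samples), s_occupied(n_samples),
      s_mrca(n_samples), s_mrca_depth(n_samples), s_dominant(n_samples),
      s_births(n_samples);
  NumericVector s_entropy(n_samples);
  IntegerMatrix s_counts(n_samples, n_tasks); // performer counts per task
  int sample_i = 0;
  long births_acc = 0;

  std::vector<int> mutbuf;
  for (int step = 0; step < n_updates; ++step) {
    int t = start_update + step;
    int row = ((t >= stage2_start) ? 2 : 0) + ((t / cycle_length) % 2);
    // merit-relative scheduling: energy gain is merit / mean merit of the
    // population at the start of the update (Avida-style CPU allocation)
    double mean_merit = 1.0;
    if (relative_scheduler) {
      double sum = 0.0;
      int occ = 0;
      for (int cell = 0; cell < N; ++cell) {
        if (grid[cell] >= 0) { sum += gts[grid[cell]].merit[row]; ++occ; }
      }
      mean_merit = (occ > 0) ? sum / occ : 0.0;
      if (mean_merit <= 0.0) mean_merit = 1.0;
    }
    for (int cell = 0; cell < N; ++cell) {
      int gid = grid[cell];
      if (gid < 0 || born_at[cell] == t) continue;
      double m = gts[gid].merit[row];
      if (m <= 0.0) continue;
      energy[cell] += relative_scheduler ? m / mean_merit : m;
      if (energy[cell] < cost) continue;
      // reproduce
      energy[cell] = 0.0;
      ++births_acc;
      int n_mut = (l > 0 && mu > 0.0) ? (int)R::rbinom((double)l, mu) : 0;
      int child_gt = gid, child_node = node[cell];
      if (n_mut > 0) {
        // distinct sites
        mutbuf.clear();
        while ((int)mutbuf.size() < n_mut) {
          int s = (int)(unif_rand() * l);
          if (s >= l) s = l - 1;
          bool dup = false;
          for (size_t q = 0; q < mutbuf.size(); ++q)
            if (mutbuf[q] == s) { dup = true; break; }
          if (!dup) mutbuf.push_back(s);
        }
        std::string g = gts[gid].genome;
        for (int q = 0; q < n_mut; ++q) {
          int s = mutbuf[q];
          int a = (int)(unif_rand() * (n_symbols - 1));
          if (a >= (int)(uint8_t)g[s]) ++a;
          g[s] = (char)a;
        }
        std::unordered_map<std::string, int>::iterator it = gt_index.find(g);
        if (it == gt_index.end()) {
          Genotype G;
          G.genome = g;
          G.mask.resize(n_tasks);
          G.viable = phenotype_of((const uint8_t *)g.data(), l, in.data(),
                                  in.size(), max_steps, tt, G.mask);
          for (int r = 0; r < 4; ++r) {
            double mm = G.viable ? 1.0 : 0.0;
            if (G.viable)
              for (int tk = 0; tk < n_tasks; ++tk)
                if (G.mask[tk]) mm *= multipliers(r, tk);
            G.merit[r] = mm;
          }
          child_gt = (int)gts.size();
          gts.push_back(G);
          gt_index[g] = child_gt;
        } else child_gt = it->second;
        // new phylogeny node (genotype-changing birth)
        child_node = (int)ph_parent.size();
        ph_parent.push_back(node[cell]);
        ph_update.push_back(t);
        ph_depth.push_back(ph_depth[node[cell]] + 1);
        ph_gt.push_back(child_gt);
        for (int q = 0; q < n_mut; ++q) {
          mut_site.push_back(mutbuf[q] + 1); // 1-based
          mut_sym.push_back((int)(uint8_t)gts[child_gt].genome[mutbuf[q]]);
        }
        ph_moff.push_back((int)mut_site.size());
      }
      int k = (int)(unif_rand() * 8);
      if (k >= 8) k = 7;
      int x = cell % W, y = cell / W;
      int nx = (x + DX[k] + W) % W, ny = (y + DY[k] + H) % H;
      int target = ny * W + nx;
      grid[target] = child_gt;
      node[target] = child_node;
      energy[target] = 0.0;
      born_at[target] = t;
    }

    bool do_sample = ((step + 1) % sampling_interval == 0) ||
                     (step == n_updates - 1);
    if (do_sample && sample_i < n_samples) {
      s_update[sample_i] = t + 1;
      // occupancy, task counts, dominant, entropy
      int occ = 0;
      std::vector<int> tcount(n_tasks, 0);
      std::unordered_map<int, int> dom;
      std::vector<int> sym_counts(l * n_symbols, 0);
      for (int cell = 0; cell < N; ++cell) {
        int gid = grid[cell];
        if (gid < 0) continue;
        ++occ;
        dom[gid] += 1;
        const Genotype &G = gts[gid];
        for (int tk = 0; tk < n_tasks; ++tk)
          if (G.mask[tk]) ++tcount[tk];
        for (int s = 0; s < l; ++s)
          ++sym_counts[s * n_symbols + (int)(uint8_t)G.genome[s]];
      }
      s_occupied[sample_i] = occ;
      for (int tk = 0; tk < n_tasks; ++tk) s_counts(sample_i, tk) = tcount[tk];
      int best = -1, bestc = -1;
      for (std::unordered_map<int, int>::iterator it = dom.begin();
           it != dom.end(); ++it)
        if (it->second > bestc || (it->second == bestc && it->first < best)) {
          best = it->first; bestc = it->second;
        }
      s_dominant[sample_i] = best + 1; // 1-based genotype index
      double hsum = 0.0;
      if (occ > 0) {
        for (int s = 0; s < l; ++s) {
          double h = 0.0;
          for (int a = 0; a < n_symbols; ++a) {
            int c = sym_counts[s * n_symbols + a];
            if (c > 0) {
              double f = (double)c / occ;
              h -= f * std::log2(f);
            }
          }
          hsum += h;
        }
      }
      s_entropy[sample_i] = (l > 0) ? hsum / l : 0.0;
      // MRCA of living organisms: repeatedly replace the deepest node by
      // its parent until one remains
      {
        std::vector<int> alive;
        for (int cell = 0; cell < N; ++cell)
          if (grid[cell] >= 0) alive.push_back(node[cell]);
        std::sort(alive.begin(), alive.end());
        alive.erase(std::unique(alive.begin(), alive.end()), alive.end());
        int mrca = -1;
        if (!alive.empty()) {
          // LCA(set) = the minimum-depth node among pairwise LCAs with a
          // reference member: mark the reference's root path, then walk
          // each other node upward to its first marked ancestor
          std::unordered_map<int, char> on_path;
          for (int v = alive[0]; v >= 0; v = ph_parent[v]) on_path[v] = 1;
          mrca = alive[0];
          for (size_t q = 1; q < alive.size() && mrca >= 0; ++q) {
            int v = alive[q];
            while (v >= 0 && on_path.find(v) == on_path.end())
              v = ph_parent[v];
            if (v < 0) { mrca = -1; break; } // disjoint roots
            if (ph_depth[v] < ph_depth[mrca]) mrca = v;
          }
        }
        s_mrca[sample_i] = (mrca >= 0) ? mrca + 1 : NA_INTEGER;
        s_mrca_depth[sample_i] = (mrca >= 0) ? ph_depth[mrca] : NA_INTEGER;
      }
      s_births[sample_i] = (int)births_acc;
      ++sample_i;
    }
  }

  // export genotypes as letter strings
  CharacterVector genomes(gts.size());
  LogicalVector gviable(gts.size());
  for (size_t i = 0; i < gts.size(); ++i) {
    std::string s(gts[i].genome.size(), 'a');
    for (size_t j = 0; j < s.size(); ++j)
      s[j] = (char)('a' + (uint8_t)gts[i].genome[j]);
    genomes[i] = s;
    gviable[i] = gts[i].viable;
  }
  IntegerVector grid_out(N), node_out(N);
  NumericVector energy_out(N);
  for (int i = 0; i < N; ++i) {
    grid_out[i] = grid[i] + 1; // 1-based; 0 means empty
    node_out[i] = node[i] + 1;
    energy_out[i] = energy[i];
  }
  return List::create(
      _["samples"] = List::create(
          _["update"] = s_update, _["occupied"] = s_occupied,
          _["entropy"] = s_entropy, _["mrca"] = s_mrca,
          _["mrca_depth"] = s_mrca_depth, _["dominant"] = s_dominant,
          _["births"] = s_births, _["task_counts"] = s_counts),
      _["phylogeny"] = List::create(
          _["parent"] = IntegerVector(ph_parent.begin(), ph_parent.end()),
          _["update"] = IntegerVector(ph_update.begin(), ph_update.end()),
          _["depth"] = IntegerVector(ph_depth.begin(), ph_depth.end()),
          _["genotype"] = IntegerVector(ph_gt.begin(), ph_gt.end()),
          _["mut_offset"] = IntegerVector(ph_moff.begin(), ph_moff.end()),
          _["mut_site"] = IntegerVector(mut_site.begin(), mut_site.end()),
          _["mut_symbol"] = IntegerVector(mut_sym.begin(), mut_sym.end())),
      _["genotypes"] = List::create(
          _["genome"] = genomes, _["viable"] = gviable),
      _["grid"] = grid_out, _["node"] = node_out, _["energy"] = energy_out,
      _["n_births"] = (double)births_acc);
}
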