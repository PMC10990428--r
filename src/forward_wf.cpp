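// Forward Wright-Fisher simulation of a species tree with exon-restricted
// selected mutations (gamma/exponential DFE), multiplicative fitness across
// sites with additive (h = 0.5) effects within a site.  Populations are
// diploid with fitness-weighted multinomial resampling; splits copy the
// parent population state into both daughters.  Fixations (derived count
// reaching 2N within a branch) are recorded and the fixed mutations removed
// from segregating haplotypes.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <functional>
#include <unordered_map>

using namespace Rcpp;

namespace {

struct MutationRegistry {
  std::vector<double> pos;   // bp position in [0, L)
  std::vector<double> s;     // selection coefficient (already Q-scaled)
  std::vector<int> cls;      // 0 neutral, 1 deleterious, 2 beneficial
  int add(double p, double sel, int c) {
    pos.push_back(p); s.push_back(sel); cls.push_back(c);
    return (int)pos.size() - 1;
  }
};

typedef std::vector<int> Hap;          // mutation ids sorted by position
typedef std::vector<Hap> Pop;          // 2N haplotypes

struct FixRec {
  int branch; double pos; int cls; double s; double gen;
};

struct Params {
  double L;
  std::vector<double> exS, exE;        // exon intervals [start, end), bp
  double muNeutralNonExon;             // per bp per gen (rescaled)
  double muNeutralExon, muDel, muBen;  // per bp per gen within exons
  double gammaShape, gammaScale;       // deleterious |s| ~ gamma
  double expMean;                      // beneficial s ~ exponential
  double sFactor;                      // Q: multiplies drawn s
  std::vector<double> rcS, rcE, rcRate;  // recombination map (rescaled)
  double totalMorgans;
  std::vector<double> cumMorgans;      // cumulative at rcE
};

struct Sim {
  Params par;
  MutationRegistry reg;
  std::mt19937_64 rng;
  std::vector<FixRec> fixations;
  double exonLen;
  double muExonTotal, muPerGamete;

  Sim(const Params& p, uint64_t seed) : par(p), rng(seed) {
    exonLen = 0.0;
    for (size_t i = 0; i < par.exS.size(); ++i) exonLen += par.exE[i] - par.exS[i];
    muExonTotal = par.muNeutralExon + par.muDel + par.muBen;
    muPerGamete = par.muNeutralNonExon * (par.L - exonLen) + muExonTotal * exonLen;
  }

  double runif() { return std::uniform_real_distribution<double>(0.0, 1.0)(rng); }

  // position uniform within exons
  double exonPos() {
    double u = runif() * exonLen;
    for (size_t i = 0; i < par.exS.size(); ++i) {
      double w = par.exE[i] - par.exS[i];
      if (u < w) return par.exS[i] + u;
      u -= w;
    }
    return par.exE.back() - 1e-9;
  }

  // position uniform outside exons
  double nonExonPos() {
    for (;;) {
      double p = runif() * par.L;
      bool inEx = false;
      for (size_t i = 0; i < par.exS.size(); ++i)
        if (p >= par.exS[i] && p < par.exE[i]) { inEx = true; break; }
      if (!inEx) return p;
    }
  }

  int drawMutation() {  // returns new mutation id
    double pExon = muExonTotal * exonLen / muPerGamete;
    if (runif() < pExon) {
      double u = runif() * muExonTotal;
      if (u < par.muDel) {
        double mag = std::gamma_distribution<double>(par.gammaShape,
                       par.gammaScale)(rng);
        double sel = -mag * par.sFactor;
        if (sel < -1.0) sel = -1.0;     // cap at lethal
        return reg.add(exonPos(), sel, 1);
      } else if (u < par.muDel + par.muBen) {
        double sel = std::exponential_distribution<double>(1.0 / par.expMean)(rng)
                     * par.sFactor;
        return reg.add(exonPos(), sel, 2);
      }
      return reg.add(exonPos(), 0.0, 0);
    }
    return reg.add(nonExonPos(), 0.0, 0);
  }

  // crossover position via inverse cumulative map
  double crossoverPos() {
    double u = runif() * par.totalMorgans;
    size_t i = std::lower_bound(par.cumMorgans.begin(), par.cumMorgans.end(), u)
               - par.cumMorgans.begin();
    if (i >= par.rcS.size()) i = par.rcS.size() - 1;
    double prev = i == 0 ? 0.0 : par.cumMorgans[i - 1];
    double within = (u - prev) / std::max(par.rcRate[i], 1e-300);
    return par.rcS[i] + within;
  }

  bool posLess(int a, int b) const {
    if (reg.pos[a] != reg.pos[b]) return reg.pos[a] < reg.pos[b];
    return a < b;
  }

  // gamete from two parental haplotypes with recombination + new mutations
  Hap makeGamete(const Hap& h1, const Hap& h2) {
    Hap out;
    int nco = (par.totalMorgans > 0)
      ? std::poisson_distribution<int>(par.totalMorgans)(rng) : 0;
    if (nco == 0) {
      out = (runif() < 0.5) ? h1 : h2;
    } else {
      std::vector<double> br(nco);
      for (int i = 0; i < nco; ++i) br[i] = crossoverPos();
      std::sort(br.begin(), br.end());
      bool useFirst = runif() < 0.5;
      out.reserve(h1.size() + h2.size());
      size_t i1 = 0, i2 = 0, bi = 0;
      double lo = 0.0;
      for (bi = 0; bi <= br.size(); ++bi) {
        double hi = bi < br.size() ? br[bi] : par.L + 1.0;
        const Hap& src = useFirst ? h1 : h2;
        size_t& ix = useFirst ? i1 : i2;
        size_t& ox = useFirst ? i2 : i1;
        while (ix < src.size() && reg.pos[src[ix]] < hi) {
          if (reg.pos[src[ix]] >= lo) out.push_back(src[ix]);
          ++ix;
        }
        const Hap& oth = useFirst ? h2 : h1;
        while (ox < oth.size() && reg.pos[oth[ox]] < hi) ++ox;
        useFirst = !useFirst;
        lo = hi;
      }
    }
    int nmut = std::poisson_distribution<int>(muPerGamete)(rng);
    for (int i = 0; i < nmut; ++i) {
      int id = drawMutation();
      auto it = std::lower_bound(out.begin(), out.end(), id,
        [this](int a, int b) { return posLess(a, b); });
      out.insert(it, id);
    }
    return out;
  }

  // additive within a site: s per allele copy (1, 1+s, 1+2s), so a new
  // mutation's heterozygous advantage is s, matching the diffusion oracle
  // u(s) = (1-e^{-2s})/(1-e^{-4Ns}); multiplicative across sites.
  double fitness(const Hap& h1, const Hap& h2) {
    double w = 1.0;
    size_t i = 0, j = 0;
    while (i < h1.size() || j < h2.size()) {
      int a = i < h1.size() ? h1[i] : -1;
      int b = j < h2.size() ? h2[j] : -1;
      double f = 1.0;
      if (a >= 0 && b >= 0 && a == b) {             // homozygous
        f = 1.0 + 2.0 * reg.s[a];
        ++i; ++j;
      } else if (b < 0 || (a >= 0 && posLess(a, b))) {
        f = 1.0 + reg.s[a];
        ++i;
      } else {
        f = 1.0 + reg.s[b];
        ++j;
      }
      if (f < 0.0) f = 0.0;
      w *= f;
    }
    return w > 0.0 ? w : 0.0;
  }

  // remove fixed mutations (count == 2N), record them; called periodically
  void sweepFixed(Pop& pop, int branch, double gen) {
    std::unordered_map<int, int> cnt;
    for (const Hap& h : pop) for (int id : h) ++cnt[id];
    int n2 = (int)pop.size();
    std::vector<int> fixed;
    for (auto& kv : cnt) if (kv.second == n2) fixed.push_back(kv.first);
    if (fixed.empty()) return;
    std::sort(fixed.begin(), fixed.end());
    for (int id : fixed)
      fixations.push_back({branch, reg.pos[id], reg.cls[id], reg.s[id], gen});
    for (Hap& h : pop) {
      Hap keep;
      keep.reserve(h.size());
      for (int id : h)
        if (!std::binary_search(fixed.begin(), fixed.end(), id))
          keep.push_back(id);
      h.swap(keep);
    }
  }

  // evolve a population for g generations at diploid size N
  void evolve(Pop& pop, int N, int gens, int branch, double gen0,
              int sweepEvery) {
    bool anySel = par.muDel > 0 || par.muBen > 0;
    std::vector<double> w;
    for (int g = 0; g < gens; ++g) {
      int Nold = (int)pop.size() / 2;
      std::function<int()> pick;
      std::discrete_distribution<int> dd;
      if (anySel) {
        w.assign(Nold, 1.0);
        bool nonunif = false;
        for (int i = 0; i < Nold; ++i) {
          w[i] = fitness(pop[2 * i], pop[2 * i + 1]);
          if (w[i] != w[0]) nonunif = true;
        }
        double tot = 0; for (double x : w) tot += x;
        if (nonunif && tot > 0) {
          dd = std::discrete_distribution<int>(w.begin(), w.end());
          pick = [&]() { return dd(rng); };
        } else {
          pick = [&]() { return (int)(runif() * Nold); };
        }
      } else {
        pick = [&]() { return (int)(runif() * Nold); };
      }
      Pop next(2 * N);
      for (int i = 0; i < N; ++i) {
        int p1 = pick(), p2 = pick();
        next[2 * i] = makeGamete(pop[2 * p1], pop[2 * p1 + 1]);
        next[2 * i + 1] = makeGamete(pop[2 * p2], pop[2 * p2 + 1]);
      }
      pop.swap(next);
      if ((g + 1) % sweepEvery == 0 || g == gens - 1)
        sweepFixed(pop, branch, gen0 + g + 1);
    }
    if (gens == 0 && (int)pop.size() != 2 * N) {
      // size change without time: resample N individuals
      Pop next(2 * N);
      int Nold = (int)pop.size() / 2;
      for (int i = 0; i < N; ++i) {
        int p = (int)(runif() * Nold);
        next[2 * i] = pop[2 * p];
        next[2 * i + 1] = pop[2 * p + 1];
      }
      pop.swap(next);
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".forwardWF")]]
List forwardWF(List treeSpec, List params, int burninGens, int sweepEvery,
               double seed) {
  // treeSpec: name (chr), parent (int, 0-based, -1 root), gens (int),
  //           N (int), isTip (lgl), nSamples (int); pre-order (parents first)
  CharacterVector bname = treeSpec["name"];
  IntegerVector parent = treeSpec["parent"];
  IntegerVector gens = treeSpec["gens"];
  IntegerVector Nv = treeSpec["N"];
  LogicalVector isTip = treeSpec["isTip"];
  IntegerVector nSamples = treeSpec["nSamples"];
  int nb = bname.size();

  Params par;
  par.L = as<double>(params["L"]);
  par.exS = as<std::vector<double> >(params["exonStart"]);
  par.exE = as<std::vector<double> >(params["exonEnd"]);
  par.muNeutralNonExon = as<double>(params["muNeutralNonExon"]);
  par.muNeutralExon = as<double>(params["muNeutralExon"]);
  par.muDel = as<double>(params["muDel"]);
  par.muBen = as<double>(params["muBen"]);
  par.gammaShape = as<double>(params["gammaShape"]);
  par.gammaScale = as<double>(params["gammaScale"]);
  par.expMean = as<double>(params["expMean"]);
  par.sFactor = as<double>(params["sFactor"]);
  par.rcS = as<std::vector<double> >(params["recombStart"]);
  par.rcE = as<std::vector<double> >(params["recombEnd"]);
  par.rcRate = as<std::vector<double> >(params["recombRate"]);
  par.cumMorgans.resize(par.rcS.size());
  double cum = 0;
  for (size_t i = 0; i < par.rcS.size(); ++i) {
    cum += par.rcRate[i] * (par.rcE[i] - par.rcS[i]);
    par.cumMorgans[i] = cum;
  }
  par.totalMorgans = cum;

  Sim sim(par, (uint64_t)seed);

  // root index: parent == -1
  int rootIdx = 0;
  for (int i = 0; i < nb; ++i) if (parent[i] < 0) rootIdx = i;

  // states held per branch index after its evolution
  std::vector<Pop> state(nb);
  std::vector<double> genAt(nb, 0.0);

  // burn-in at the root ancestral size
  {
    Pop pop(2 * Nv[rootIdx]);
    sim.evolve(pop, Nv[rootIdx], burninGens, rootIdx, -burninGens, sweepEvery);
    state[rootIdx] = pop;
    genAt[rootIdx] = 0.0;
  }

  // pre-order traversal: each non-root branch copies its parent's end state
  for (int i = 0; i < nb; ++i) {
    if (i == rootIdx) continue;
    Pop pop = state[parent[i]];   // copy (split replicates the population)
    sim.evolve(pop, Nv[i], gens[i], i, genAt[parent[i]], sweepEvery);
    state[i] = pop;
    genAt[i] = genAt[parent[i]] + gens[i];
  }

  // sample tips
  List tipHaps(nb);
  for (int i = 0; i < nb; ++i) {
    if (!isTip[i]) continue;
    Pop& pop = state[i];
    int N = (int)pop.size() / 2;
    int ns = std::min(nSamples[i], N);
    // sample ns diploids without replacement
    std::vector<int> idx(N);
    for (int k = 0; k < N; ++k) idx[k] = k;
    for (int k = 0; k < ns; ++k) {
      int j = k + (int)(sim.runif() * (N - k));
      std::swap(idx[k], idx[j]);
    }
    List haps(2 * ns);
    for (int k = 0; k < ns; ++k) {
      haps[2 * k] = wrap(pop[2 * idx[k]]);
      haps[2 * k + 1] = wrap(pop[2 * idx[k] + 1]);
    }
    tipHaps[i] = haps;
  }

  int nf = (int)sim.fixations.size();
  IntegerVector fb(nf), fc(nf);
  NumericVector fp(nf), fs(nf), fg(nf);
  for (int i = 0; i < nf; ++i) {
    fb[i] = sim.fixations[i].branch + 1;  // 1-based branch index
    fp[i] = sim.fixations[i].pos;
    fc[i] = sim.fixations[i].cls;
    fs[i] = sim.fixations[i].s;
    fg[i] = sim.fixations[i].gen;
  }

  return List::create(
    _["tipHaps"] = tipHaps,
    _["mutPos"] = wrap(sim.reg.pos),
    _["mutS"] = wrap(sim.reg.s),
    _["mutClass"] = wrap(sim.reg.cls),
    _["fixBranch"] = fb, _["fixPos"] = fp, _["fixClass"] = fc,
    _["fixS"] = fs, _["fixGen"] = fg);
}
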