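// Monte Carlo core of the RNA-world / protocell lattice simulator.
//
// The grid is an N x N torus of "rooms". A room holds molecule pools
// (nucleotide precursors, free nucleotides per letter, amphiphile
// precursors, free amphiphiles), free RNA strands, template complexes
// (template + aligned substrates, optionally a bound REP with a growing
// product), and at most one protocell. A protocell occupies its room
// entirely: its interior is a compartment of the same kind, and all free
// molecules "outside" it belong to the neighbouring rooms.
//
// Letters are encoded A=0, C=1, G=2, U=3; the Watson-Crick complement of x
// is 3-x. Sequences are stored 5'->3'. An aligned partner with offset `off`
// and length L covers template positions [off, off+L-1], antiparallel:
// partner[j] pairs template[off+L-1-j].

#include <Rcpp.h>
#include <random>
#include <vector>
#include <memory>
#include <algorithm>
#include <cstdint>
#include <cmath>
#include <chrono>
#include <string>

using namespace Rcpp;

typedef long long ll;

// xoshiro256++ bit generator (fast, 64-bit, single stream), seeded via
// splitmix64 so any 64-bit seed expands to a full state
struct Xoshiro {
  typedef uint64_t result_type;
  uint64_t s[4];
  static constexpr uint64_t min() { return 0; }
  static constexpr uint64_t max() { return ~0ULL; }
  void seed(uint64_t x) {
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t operator()() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0];
    s[3] ^= s[1];
    s[1] ^= s[2];
    s[0] ^= s[3];
    s[2] ^= t;
    s[3] = rotl(s[3], 45);
    return result;
  }
};

// ---------------------------------------------------------------- parameters

struct Pars {
  double P_AT, P_BB, P_FLR, P_FP, P_MV, P_ND, P_NDE, P_NF, P_NFR, P_RBT,
      P_RD, P_RL, P_RTT, P_SP, P_TL, P_TLR, P_AD, P_ADM, P_AF, P_AJM, P_ALM,
      P_APP, P_CB, P_CC, P_CD, P_CF, P_MC, P_MF, P_NPP;
  double F_OP, F_DE;
  int N, C_T, L_AM;
  ll T_NPB, T_APB;
};

struct RegionProfile {
  double mv_mult = 1, degr_mult = 1, syn_mult = 1;
  bool protocells_allowed = false;
};

static double clamp01(double x) { return x < 0 ? 0 : (x > 1 ? 1 : x); }

// closed-form event probabilities (the same rules the R layer exposes)
static double f_separation(int r, double psp) {
  return std::pow(psp, (r + 1) / 2.0);
}
static double f_bond_break(bool double_chain, double pbb) {
  return double_chain ? std::pow(pbb, 1.5) : pbb;
}
static double f_membrane(ll a, double pmf, int lam) {
  if (a < lam) return 0.0;
  return 1.0 - std::pow(1.0 - pmf, (double)(a - lam + 1));
}
static double f_leave(ll b, ll n, double palm, double fop) {
  return palm / (1.0 + fop * (double)n / std::pow(b / 2.0, 1.5));
}
static double f_perm_in(ll b, ll n, double pnpp, int lam, double fde) {
  double p = pnpp * ((double)b / lam) /
             (1.0 + fde * (double)n / std::pow(b / 2.0, 1.5));
  return clamp01(p);
}
static double f_division(ll b, double pcd, int lam) {
  double p = pcd * (1.0 - 2.0 * (double)lam / (double)b);
  return p > 0 ? p : 0;
}
static double f_move(int m, double pmv) { return pmv / std::sqrt((double)m); }

// --------------------------------------------------------------- sequences

typedef std::vector<uint8_t> Seq;

static Seq encode_seq(const std::string& s) {
  Seq out(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    switch (s[i]) {
      case 'A': out[i] = 0; break;
      case 'C': out[i] = 1; break;
      case 'G': out[i] = 2; break;
      case 'U': out[i] = 3; break;
      default: stop("invalid RNA symbol '%c'", s[i]);
    }
  }
  return out;
}
static std::string decode_seq(const Seq& s) {
  static const char* L = "ACGU";
  std::string out(s.size(), 'A');
  for (size_t i = 0; i < s.size(); ++i) out[i] = L[s[i]];
  return out;
}
static Seq revcomp(const Seq& s) {
  Seq out(s.size());
  for (size_t i = 0; i < s.size(); ++i) out[i] = 3 - s[s.size() - 1 - i];
  return out;
}
static bool starts_with(const Seq& s, const Seq& pre) {
  if (s.size() < pre.size()) return false;
  return std::equal(pre.begin(), pre.end(), s.begin());
}
static bool ends_with(const Seq& s, const Seq& suf) {
  if (s.size() < suf.size()) return false;
  return std::equal(suf.rbegin(), suf.rend(), s.rbegin());
}
static bool contains(const Seq& s, const Seq& pat) {
  if (pat.empty() || s.size() < pat.size()) return false;
  return std::search(s.begin(), s.end(), pat.begin(), pat.end()) != s.end();
}

// role flags
enum {
  RF_REP = 1, RF_REP_SPR = 2, RF_NSR = 4, RF_NSR_SPR = 8,
  RF_PARA = 16, RF_PLAIN = 32,
  // species membership for molecule counts: carries the catalytic domain
  // (sense orientation), with or without an intact tag
  RF_REP_DOM = 64, RF_NSR_DOM = 128
};

struct SeqSet { Seq tag, rep, nsr, rep_rc, nsr_rc, tag_rep; };

static uint32_t classify_seq(const Seq& s, const SeqSet& cs) {
  uint32_t f = 0;
  bool rep_fun = starts_with(s, cs.tag_rep);
  bool nsr_fun = contains(s, cs.nsr);
  if (contains(s, cs.rep)) f |= RF_REP_DOM;
  if (nsr_fun) f |= RF_NSR_DOM;
  if (rep_fun) {
    f |= RF_REP;
    if (ends_with(s, cs.tag) &&
        s.size() >= cs.tag.size() * 2 + cs.rep.size())
      f |= RF_REP_SPR;
  }
  if (nsr_fun) {
    f |= RF_NSR;
    Seq spr = cs.tag;
    spr.insert(spr.end(), cs.nsr.begin(), cs.nsr.end());
    spr.insert(spr.end(), cs.tag.begin(), cs.tag.end());
    if (s == spr) f |= RF_NSR_SPR;
  }
  bool has_domain = rep_fun || nsr_fun || contains(s, cs.rep) ||
                    contains(s, cs.rep_rc) || contains(s, cs.nsr_rc);
  if (!has_domain && s.size() >= 2 * cs.tag.size() &&
      starts_with(s, cs.tag) && ends_with(s, cs.tag))
    f |= RF_PARA;
  if (!(f & (RF_REP | RF_NSR | RF_PARA))) f |= RF_PLAIN;
  return f;
}

// ------------------------------------------------------------------- agents

struct Strand {
  Seq seq;
  uint32_t flags = 0;
  // non-enzymatic template decision, made once per single-strand episode at
  // the first attraction opportunity: 0 undecided, 1 template, 2 declined
  // (a REP binding onto the strand overrides the decision)
  uint8_t tstate = 0;
};

struct Aligned {
  int off;        // template position of the partner's 3'-most pairing
  Seq seq;        // 5'->3'; seq[j] pairs template[off+len-1-j]
};

struct Complex {
  Strand tpl;
  std::vector<Aligned> subs;   // sorted by off
  bool has_rep = false;
  Strand rep;
  int copied = 0;              // residues of the product synthesized so far
  Seq product;                 // product[j] pairs tpl[n-1-j]
  std::vector<uint8_t> prod_mm;
  bool recognition_paired = false;
};

struct Pools {
  ll np = 0, nt[4] = {0, 0, 0, 0}, ap = 0, am = 0;
  ll nt_total() const { return nt[0] + nt[1] + nt[2] + nt[3]; }
};

struct Cell {
  ll b = 0;          // membrane amphiphile count
  Pools pools;
  std::vector<Strand> strands;
  std::vector<Complex> cxs;
  ll n_cache = 0;    // interior impermeable ions: free nt + RNA residues
};

struct Room {
  Pools pools;
  std::vector<Strand> strands;
  std::vector<Complex> cxs;
  std::unique_ptr<Cell> cell;
  uint8_t region = 0;  // 0 rocky, 1 solution
};

// event-frequency counters (attempts, successes) for wiring checks
enum EvId {
  EV_NF, EV_NFR, EV_ND, EV_AF, EV_AD, EV_ADM, EV_NDE, EV_RL, EV_TL, EV_TLR,
  EV_FLR, EV_RBT, EV_RTT, EV_RD, EV_AT, EV_CB, EV_CF, EV_MC, EV_CC, EV_AJM,
  EV_MV_R0, EV_MV_R1, EV_CD, EV_SEP, EV_STALL_BLOCK, EV_STALL_LETTER,
  EV_N_
};
static const char* EV_NAMES[EV_N_] = {
  "nucleotide_formation", "nucleotide_formation_nsr", "nucleotide_decay",
  "amphiphile_formation", "amphiphile_decay", "membrane_amphiphile_decay",
  "end_residue_decay", "random_ligation", "template_ligation",
  "rep_ligation", "rep_false_ligation", "rep_bind", "turn_to_template",
  "rep_drop", "attract", "cell_break", "cell_fusion", "cell_move",
  "cytophagy", "membrane_join", "pool_move_rocky", "pool_move_solution",
  "cell_division", "separation", "rep_stall_blocked", "rep_stall_no_letter"
};

// ---------------------------------------------------------------------- sim

struct Sim {
  Pars base;
  RegionProfile prof[2];
  Pars eff[2][2];  // [region][inside_protocell]
  SeqSet cs;
  int N = 0;
  int interface_policy = 1;  // 0 = precursors_only, 1 = all_molecules
  std::vector<Room> rooms;
  std::vector<std::array<int, 4> > nbr;
  ll step_count = 0;
  Xoshiro rng;
  long double nt_expected = 0, am_expected = 0;
  ll ev_att[EV_N_] = {0}, ev_suc[EV_N_] = {0};
  int ledger_every = 1000;
  double phase_ns[5] = {0, 0, 0, 0, 0};

  // --- rng helpers
  double runif01() {
    return ((*this).rng() >> 11) * 0x1.0p-53;
  }
  bool bern(double p, EvId id) {
    ev_att[id]++;
    bool s = p >= 1.0 || (p > 0.0 && runif01() < p);
    if (s) ev_suc[id]++;
    return s;
  }
  bool bern(double p) {
    return p >= 1.0 || (p > 0.0 && runif01() < p);
  }
  ll binom(ll n, double p, EvId id) {
    ev_att[id] += n;
    ll k = binom(n, p);
    ev_suc[id] += k;
    return k;
  }
  ll binom(ll n, double p) {
    if (n <= 0 || p <= 0) return 0;
    if (p >= 1) return n;
    std::binomial_distribution<ll> d(n, p);
    return d(rng);
  }
  int randint(int n) {  // uniform on [0, n)
    return (int)(rng() % (uint64_t)n);
  }

  void rebuild_eff() {
    for (int r = 0; r < 2; ++r)
      for (int in = 0; in < 2; ++in) {
        Pars p = base;
        const RegionProfile& pr = prof[r];
        p.P_MV = clamp01(p.P_MV * pr.mv_mult);
        p.P_RL = clamp01(p.P_RL * pr.syn_mult);
        p.P_NF = clamp01(p.P_NF * pr.syn_mult);
        if (!in) {
          p.P_BB = clamp01(p.P_BB * pr.degr_mult);
          p.P_ND = clamp01(p.P_ND * pr.degr_mult);
          p.P_NDE = clamp01(p.P_NDE * pr.degr_mult);
          p.P_AD = clamp01(p.P_AD * pr.degr_mult);
        }
        eff[r][in] = p;
      }
  }

  void build_grid(const IntegerVector& region) {
    rooms.clear();
    rooms.resize((size_t)N * N);
    nbr.resize((size_t)N * N);
    for (int y = 0; y < N; ++y)
      for (int x = 0; x < N; ++x) {
        int i = y * N + x;
        rooms[i].region = (uint8_t)region[i];
        nbr[i][0] = y * N + ((x + 1) % N);
        nbr[i][1] = y * N + ((x + N - 1) % N);
        nbr[i][2] = ((y + 1) % N) * N + x;
        nbr[i][3] = ((y + N - 1) % N) * N + x;
      }
  }

  // --- ledgers
  static ll complex_residues(const Complex& c) {
    ll r = (ll)c.tpl.seq.size();
    for (const Aligned& a : c.subs) r += (ll)a.seq.size();
    if (c.has_rep) r += (ll)c.rep.seq.size();
    r += (ll)c.product.size();
    return r;
  }
  static ll compartment_residues(const std::vector<Strand>& ss,
                                 const std::vector<Complex>& cc) {
    ll r = 0;
    for (const Strand& s : ss) r += (ll)s.seq.size();
    for (const Complex& c : cc) r += complex_residues(c);
    return r;
  }
  ll nt_equivalents() const {
    ll tot = 0;
    for (const Room& rm : rooms) {
      tot += rm.pools.np + rm.pools.nt_total();
      tot += compartment_residues(rm.strands, rm.cxs);
      if (rm.cell) {
        tot += rm.cell->pools.np + rm.cell->pools.nt_total();
        tot += compartment_residues(rm.cell->strands, rm.cell->cxs);
      }
    }
    return tot;
  }
  ll am_equivalents() const {
    ll tot = 0;
    for (const Room& rm : rooms) {
      tot += rm.pools.ap + rm.pools.am;
      if (rm.cell) tot += rm.cell->b + rm.cell->pools.ap + rm.cell->pools.am;
    }
    return tot;
  }
  static ll cell_n_recompute(const Cell& c) {
    return c.pools.nt_total() + compartment_residues(c.strands, c.cxs);
  }
  void check_ledgers() {
    ll nt = nt_equivalents(), am = am_equivalents();
    if (nt != (ll)nt_expected || am != (ll)am_expected)
      stop("conservation ledger violated at step %lld: nucleotide-equiv "
           "%lld (expected %lld), amphiphile-equiv %lld (expected %lld)",
           step_count, nt, (ll)nt_expected, am, (ll)am_expected);
    for (const Room& rm : rooms)
      if (rm.cell && rm.cell->n_cache != cell_n_recompute(*rm.cell))
        stop("protocell ion ledger violated at step %lld: cached n=%lld, "
             "recomputed %lld", step_count, rm.cell->n_cache,
             cell_n_recompute(*rm.cell));
  }

  // --- strand helpers -------------------------------------------------
  // add a strand to a compartment; a 1-nt strand is a free nucleotide
  static void add_strand(Pools& pools, std::vector<Strand>& strands,
                         Seq seq, const SeqSet& cs) {
    if (seq.size() == 1) {
      pools.nt[seq[0]]++;
      return;
    }
    Strand s;
    s.flags = classify_seq(seq, cs);
    s.seq = std::move(seq);
    strands.push_back(std::move(s));
  }

  // ======================================================== compartment view
  struct Comp {
    Pools* pools;
    std::vector<Strand>* strands;
    std::vector<Complex>* cxs;
    Cell* cell;       // nullptr for a plain room
    const Pars* P;
    int room;
  };
  Comp room_comp(int i) {
    Room& rm = rooms[i];
    return Comp{&rm.pools, &rm.strands, &rm.cxs, nullptr,
                &eff[rm.region][0], i};
  }
  Comp cell_comp(int i) {
    Room& rm = rooms[i];
    Cell* c = rm.cell.get();
    return Comp{&c->pools, &c->strands, &c->cxs, c, &eff[rm.region][1], i};
  }
  // adding a strand from material already inside the compartment is
  // n-neutral (nucleotides and residues weigh the same in the ion tally)
  void comp_add_strand(Comp& c, Seq seq) {
    add_strand(*c.pools, *c.strands, std::move(seq), cs);
  }

  // ============================================================= chemistry
  void phase_chemistry(Comp c) {
    const Pars& P = *c.P;
    bool nsr = false;
    for (const Strand& s : *c.strands)
      if (s.flags & RF_NSR) { nsr = true; break; }
    // nucleotide formation
    ll k = nsr ? binom(c.pools->np, P.P_NFR, EV_NFR)
               : binom(c.pools->np, P.P_NF, EV_NF);
    if (k > 0) {
      c.pools->np -= k;
      ll rem = k;
      for (int l = 0; l < 3; ++l) {
        ll kl = binom(rem, 1.0 / (4 - l));
        c.pools->nt[l] += kl;
        rem -= kl;
      }
      c.pools->nt[3] += rem;
      if (c.cell) c.cell->n_cache += k;
    }
    // nucleotide decay: draw the total, then attribute letters
    ll ntt = c.pools->nt_total();
    ll dec = binom(ntt, P.P_ND, EV_ND);
    for (ll q = 0; q < dec; ++q) {
      int l = draw_letter(c.pools->nt, ntt - q);
      c.pools->nt[l]--;
    }
    c.pools->np += dec;
    if (c.cell) c.cell->n_cache -= dec;
    // amphiphile formation / decay (precursors and amphiphiles are not part
    // of the ion tally n)
    if (c.pools->ap > 0) {
      ll af = binom(c.pools->ap, P.P_AF, EV_AF);
      c.pools->ap -= af;
      c.pools->am += af;
    }
    if (c.pools->am > 0) {
      ll ad = binom(c.pools->am, P.P_AD, EV_AD);
      c.pools->am -= ad;
      c.pools->ap += ad;
    }
  }

  // membrane amphiphile decay: decayed units leave as precursors outside
  void membrane_decay(int i) {
    Room& rm = rooms[i];
    Cell& cell = *rm.cell;
    ll k = binom(cell.b, base.P_ADM, EV_ADM);
    if (k <= 0) return;
    cell.b -= k;
    std::vector<int> tgt = open_neighbors(i);
    if (tgt.empty()) {
      cell.pools.ap += k;  // nowhere outside: deposit inside
    } else {
      for (ll j = 0; j < k; ++j)
        rooms[tgt[randint((int)tgt.size())]].pools.ap++;
    }
  }

  std::vector<int> open_neighbors(int i) {  // adjacent rooms with no cell
    std::vector<int> out;
    for (int d = 0; d < 4; ++d)
      if (!rooms[nbr[i][d]].cell) out.push_back(nbr[i][d]);
    return out;
  }

  // ============================================================ collisions
  // Coverage mask of a template within a complex (true = paired position).
  // Returns a reference to a scratch buffer valid until the next call.
  std::vector<uint8_t> sc_cov;
  const std::vector<uint8_t>& coverage(const Complex& cx) {
    std::vector<uint8_t>& cov = sc_cov;
    cov.assign(cx.tpl.seq.size(), 0);
    for (const Aligned& a : cx.subs)
      for (size_t q = 0; q < a.seq.size(); ++q) cov[a.off + q] = 1;
    size_t n = cx.tpl.seq.size();
    for (int q = 0; q < cx.copied; ++q) cov[n - 1 - q] = 1;
    if (cx.has_rep && cx.recognition_paired)
      for (size_t q = 0; q < cs.tag.size() && q < n; ++q) cov[q] = 1;
    return cov;
  }

  // try to align `sub` on template of cx given P_AT already succeeded;
  // returns true and installs the substrate if annealing holds
  bool try_align(Complex& cx, const Seq& sub, const Pars& P) {
    const Seq& tpl = cx.tpl.seq;
    int n = (int)tpl.size(), L = (int)sub.size();
    if (L > n) return false;
    const std::vector<uint8_t>& cov = coverage(cx);
    int best = -1;
    std::vector<int>& cand = sc_cand;
    cand.clear();
    for (int off = 0; off + L <= n; ++off) {
      bool free_run = true;
      for (int q = off; q < off + L; ++q)
        if (cov[q]) { free_run = false; break; }
      if (!free_run) continue;
      int score = 0;
      for (int j = 0; j < L; ++j)
        if (sub[j] + tpl[off + L - 1 - j] == 3) score++;
      if (score > best) { best = score; cand.clear(); }
      if (score == best) cand.push_back(off);
    }
    if (best < 0) return false;
    int off = cand[randint((int)cand.size())];
    // every mismatched position must pass the false-pairing trial
    for (int j = 0; j < L; ++j)
      if (sub[j] + tpl[off + L - 1 - j] != 3 && !bern(P.P_FP)) return false;
    Aligned a;
    a.off = off;
    a.seq = sub;
    cx.subs.push_back(std::move(a));
    std::sort(cx.subs.begin(), cx.subs.end(),
              [](const Aligned& x, const Aligned& y) { return x.off < y.off; });
    return true;
  }

  // one collision pairing between two free strands (indices into comp)
  // Entity encoding inside collision rounds:
  //   kind 0 = free strand (idx into strands)
  //   kind 1 = mononucleotide (letter)
  //   kind 2 = complex template (idx into cxs, REP-free complexes only)
  struct Ent { uint8_t kind; int idx; };

  // all C_T collision rounds of one compartment; rooms holding only
  // mononucleotides collapse to a single random-ligation draw
  void collision_rounds(Comp c, int rounds) {
    if (c.strands->empty() && c.cxs->empty()) {
      ll M = c.pools->nt_total();
      if (M < 2) return;
      ll lig = binom((ll)rounds * (M / 2), c.P->P_RL, EV_RL);
      for (ll q = 0; q < lig; ++q) {
        ll tot = c.pools->nt_total();
        if (tot < 2) break;
        int la = draw_letter(c.pools->nt, tot);
        c.pools->nt[la]--;
        int lb = draw_letter(c.pools->nt, tot - 1);
        c.pools->nt[lb]--;
        Seq dimer;
        if (bern(0.5)) { dimer.push_back(la); dimer.push_back(lb); }
        else { dimer.push_back(lb); dimer.push_back(la); }
        comp_add_strand(c, dimer);
      }
      return;
    }
    for (int r = 0; r < rounds; ++r) collision_round(c);
  }

  std::vector<Ent> sc_ents;
  std::vector<int> sc_rm_s, sc_rm_c, sc_cand;

  void collision_round(Comp c) {
    const Pars& P = *c.P;
    std::vector<Strand>& ss = *c.strands;
    std::vector<Complex>& cc = *c.cxs;
    // collect entities: free strands and REP-free template complexes pair
    // uniformly at random with each other and with mononucleotides
    sc_ents.clear();
    for (int i = 0; i < (int)ss.size(); ++i) sc_ents.push_back(Ent{0, i});
    for (int i = 0; i < (int)cc.size(); ++i)
      if (!cc[i].has_rep) sc_ents.push_back(Ent{2, i});
    ll mono[4];
    for (int l = 0; l < 4; ++l) mono[l] = c.pools->nt[l];
    ll Mr = mono[0] + mono[1] + mono[2] + mono[3];
    size_t n_avail = sc_ents.size();
    if ((ll)n_avail + Mr < 2) return;
    for (size_t i = n_avail; i > 1; --i)
      std::swap(sc_ents[i - 1], sc_ents[randint((int)i)]);
    sc_rm_s.clear();
    sc_rm_c.clear();
    while (n_avail > 0) {
      Ent e = sc_ents[n_avail - 1];
      n_avail--;
      ll pool = (ll)n_avail + Mr;
      if (pool == 0) break;
      bool is_mono = (ll)(runif01() * (double)pool) >= (ll)n_avail;
      if (is_mono) {
        ll pick = (ll)(runif01() * (double)Mr);
        int letter = 0;
        for (int l = 0; l < 4; ++l) {
          if (pick < mono[l]) { letter = l; break; }
          pick -= mono[l];
        }
        Mr--;
        mono[letter]--;
        resolve_strand_mono(c, e, letter, sc_rm_s, sc_rm_c);
      } else {
        int j = randint((int)n_avail);
        Ent f = sc_ents[j];
        sc_ents[j] = sc_ents[n_avail - 1];
        n_avail--;
        resolve_pair(c, e, f, sc_rm_s, sc_rm_c);
      }
    }
    // leftover mononucleotide pairs: random ligation only
    ll pairs = Mr / 2;
    ll lig = binom(pairs, P.P_RL, EV_RL);
    for (ll q = 0; q < lig; ++q) {
      ll tot = mono[0] + mono[1] + mono[2] + mono[3];
      if (tot < 2) break;
      int la = draw_letter(mono, tot);
      mono[la]--;
      int lb = draw_letter(mono, tot - 1);
      mono[lb]--;
      c.pools->nt[la]--;
      c.pools->nt[lb]--;
      Seq dimer;
      if (bern(0.5)) { dimer.push_back(la); dimer.push_back(lb); }
      else { dimer.push_back(lb); dimer.push_back(la); }
      comp_add_strand(c, dimer);
    }
    drop_indices(ss, sc_rm_s);
    drop_indices(cc, sc_rm_c);
  }

  // once-per-episode template decision at the first attraction opportunity
  bool decides_template(Strand& s, const Pars& P) {
    if (s.tstate == 0)
      s.tstate = bern(P.P_RTT, EV_RTT) ? 1 : 2;
    return s.tstate == 1;
  }

  int draw_letter(ll mono[4], ll tot) {
    ll pick = (ll)(runif01() * (double)tot);
    for (int l = 0; l < 4; ++l) {
      if (pick < mono[l]) return l;
      pick -= mono[l];
    }
    return 3;
  }

  template <class T>
  static void drop_indices(std::vector<T>& v, std::vector<int>& idx) {
    if (idx.empty()) return;
    std::sort(idx.begin(), idx.end());
    idx.erase(std::unique(idx.begin(), idx.end()), idx.end());
    for (int k = (int)idx.size() - 1; k >= 0; --k)
      v.erase(v.begin() + idx[k]);
    idx.clear();
  }

  void resolve_strand_mono(Comp c, Ent e, int letter,
                           std::vector<int>& rm_s, std::vector<int>& rm_c) {
    const Pars& P = *c.P;
    Seq sub(1, (uint8_t)letter);
    if (e.kind == 0) {
      Strand& s = (*c.strands)[e.idx];
      if (s.seq.size() >= 5 && decides_template(s, P)) {
        // template attracts the mononucleotide
        if (bern(P.P_AT, EV_AT)) {
          Complex cx;
          cx.tpl = s;
          if (try_align(cx, sub, P)) {
            c.pools->nt[letter]--;
            rm_s.push_back(e.idx);
            c.cxs->push_back(std::move(cx));
          }
        }
      } else {
        // too short to be a template: random end-to-end ligation
        if (bern(P.P_RL, EV_RL)) {
          c.pools->nt[letter]--;
          Seq joined;
          if (bern(0.5)) {
            joined = s.seq; joined.push_back((uint8_t)letter);
          } else {
            joined.push_back((uint8_t)letter);
            joined.insert(joined.end(), s.seq.begin(), s.seq.end());
          }
          rm_s.push_back(e.idx);
          comp_add_strand(c, joined);
        }
      }
    } else {  // complex template gathering further substrates
      Complex& cx = (*c.cxs)[e.idx];
      if (bern(P.P_AT, EV_AT) && try_align(cx, sub, P))
        c.pools->nt[letter]--;
    }
  }

  void resolve_pair(Comp c, Ent a, Ent b,
                    std::vector<int>& rm_s, std::vector<int>& rm_c) {
    const Pars& P = *c.P;
    if (a.kind == 0 && b.kind == 0) {
      Strand& sa = (*c.strands)[a.idx];
      Strand& sb = (*c.strands)[b.idx];
      // (ii) REP binding onto a tagged template has priority
      bool a_rep = (sa.flags & RF_REP) != 0;
      bool b_rep = (sb.flags & RF_REP) != 0;
      bool a_tagged = sa.seq.size() >= 5 && starts_with(sa.seq, cs.tag);
      bool b_tagged = sb.seq.size() >= 5 && starts_with(sb.seq, cs.tag);
      int rep_i = -1, tpl_i = -1;
      if (a_rep && b_tagged && b_rep && a_tagged) {
        if (bern(0.5)) { rep_i = a.idx; tpl_i = b.idx; }
        else { rep_i = b.idx; tpl_i = a.idx; }
      } else if (a_rep && b_tagged) { rep_i = a.idx; tpl_i = b.idx; }
      else if (b_rep && a_tagged) { rep_i = b.idx; tpl_i = a.idx; }
      if (rep_i >= 0) {
        if (bern(P.P_RBT, EV_RBT)) {
          Complex cx;
          cx.tpl = (*c.strands)[tpl_i];
          cx.rep = (*c.strands)[rep_i];
          cx.has_rep = true;
          cx.recognition_paired = true;
          cx.copied = 0;
          rm_s.push_back(rep_i);
          rm_s.push_back(tpl_i);
          c.cxs->push_back(std::move(cx));
        }
        return;
      }
      // (iii) the longer strand acts as template for the shorter
      int tpl_j, sub_j;
      size_t la = sa.seq.size(), lb = sb.seq.size();
      if (la == lb) { if (bern(0.5)) { tpl_j = a.idx; sub_j = b.idx; }
                      else { tpl_j = b.idx; sub_j = a.idx; } }
      else if (la > lb) { tpl_j = a.idx; sub_j = b.idx; }
      else { tpl_j = b.idx; sub_j = a.idx; }
      if ((*c.strands)[tpl_j].seq.size() >= 5 &&
          decides_template((*c.strands)[tpl_j], P)) {
        if (bern(P.P_AT, EV_AT)) {
          Complex cx;
          cx.tpl = (*c.strands)[tpl_j];
          if (try_align(cx, (*c.strands)[sub_j].seq, P)) {
            rm_s.push_back(tpl_j);
            rm_s.push_back(sub_j);
            c.cxs->push_back(std::move(cx));
          }
        }
        return;
      }
      // (i) random ligation
      if (bern(P.P_RL, EV_RL)) {
        Seq joined;
        if (bern(0.5)) {
          joined = sa.seq;
          joined.insert(joined.end(), sb.seq.begin(), sb.seq.end());
        } else {
          joined = sb.seq;
          joined.insert(joined.end(), sa.seq.begin(), sa.seq.end());
        }
        rm_s.push_back(a.idx);
        rm_s.push_back(b.idx);
        comp_add_strand(c, joined);
      }
      return;
    }
    // complex template paired with a free strand: REP binding (if the free
    // strand is a REP and the template's 5' tag is single-stranded) takes
    // priority over substrate attraction
    if (a.kind + b.kind == 2 && a.kind != b.kind) {
      Ent ce = a.kind == 2 ? a : b;
      Ent se = a.kind == 2 ? b : a;
      Complex& cx = (*c.cxs)[ce.idx];
      Strand& s = (*c.strands)[se.idx];
      if ((s.flags & RF_REP) && !cx.has_rep && tag_recognizable(cx)) {
        if (bern(P.P_RBT, EV_RBT)) {
          cx.rep = s;
          cx.has_rep = true;
          cx.recognition_paired = true;
          cx.copied = 0;
          // a partial product still annealed at the template's 3' end is
          // adopted and extended further (primer extension)
          int n = (int)cx.tpl.seq.size();
          for (size_t q = 0; q < cx.subs.size(); ++q) {
            const Aligned& al = cx.subs[q];
            if (al.off + (int)al.seq.size() == n) {
              cx.product = al.seq;
              cx.copied = (int)al.seq.size();
              cx.prod_mm.assign(al.seq.size(), 0);
              if (cx.copied >= n - (int)cs.tag.size())
                cx.recognition_paired = false;
              cx.subs.erase(cx.subs.begin() + q);
              break;
            }
          }
          rm_s.push_back(se.idx);
        }
        return;
      }
      if (bern(P.P_AT, EV_AT) && try_align(cx, s.seq, P))
        rm_s.push_back(se.idx);
      return;
    }
    // complex-complex: no event
  }

  // a complex template is recognizable by a REP when it carries a 5' tag
  // that is not base-paired to any substrate
  bool tag_recognizable(Complex& cx) {
    if (cx.tpl.seq.size() < 5 || !starts_with(cx.tpl.seq, cs.tag))
      return false;
    const std::vector<uint8_t>& cov = coverage(cx);
    for (size_t q = 0; q < cs.tag.size(); ++q)
      if (cov[q]) return false;
    return true;
  }

  // ======================================================== polymer phase
  void phase_polymer(Comp c) {
    std::vector<Complex>& cc = *c.cxs;
    std::vector<int> dead_cxs;
    for (int ci = 0; ci < (int)cc.size(); ++ci) {
      Complex& cx = cc[ci];
      if (cx.has_rep) rep_extend(c, cx);
      if (!cx.has_rep) template_ligation(c, cx);
      separations(c, cx);
      if (!cx.has_rep && cx.subs.empty() && cx.product.empty()) {
        comp_add_strand(c, cx.tpl.seq);
        dead_cxs.push_back(ci);
      }
    }
    drop_indices(cc, dead_cxs);
    bond_breaking(c);
    end_decay(c);
  }

  void rep_extend(Comp c, Complex& cx) {
    const Pars& P = *c.P;
    int n = (int)cx.tpl.seq.size();
    if (cx.copied < n) {
      int pos = n - 1 - cx.copied;
      // a substrate annealed over the next position blocks the polymerase
      // until it separates (no strand displacement)
      bool blocked = false;
      for (const Aligned& a : cx.subs)
        if (a.off <= pos && pos < a.off + (int)a.seq.size()) {
          blocked = true;
          break;
        }
      int want = 3 - cx.tpl.seq[pos];
      if (blocked) ev_att[EV_STALL_BLOCK]++;
      else if (c.pools->nt[want] <= 0) ev_att[EV_STALL_LETTER]++;
      if (!blocked && bern(P.P_AT)) {
        int letter = -1;
        bool mm = false;
        if (bern(P.P_FP)) {  // false incorporation of a wrong letter
          std::vector<int> wrong;
          for (int l = 0; l < 4; ++l)
            if (l != want && c.pools->nt[l] > 0) wrong.push_back(l);
          if (!wrong.empty()) {
            letter = wrong[randint((int)wrong.size())];
            mm = true;
          }
        }
        if (letter < 0 && c.pools->nt[want] > 0) letter = want;
        if (letter >= 0) {
          bool ok;
          if (cx.copied == 0) {
            ok = true;  // first residue: placement, no junction to ligate
          } else {
            bool err = mm || cx.prod_mm.back();
            ok = err ? bern(P.P_FLR, EV_FLR) : bern(P.P_TLR, EV_TLR);
          }
          if (ok) {
            c.pools->nt[letter]--;
            cx.product.push_back((uint8_t)letter);
            cx.prod_mm.push_back(mm ? 1 : 0);
            cx.copied++;
            if (cx.copied >= n - (int)cs.tag.size())
              cx.recognition_paired = false;  // copying reached the 5' tag
          }
        }
      }
    }
    if (cx.copied == n) {        // full chain copied: the REP drops
      unbind_rep(c, cx);
      return;
    }
    if (bern(P.P_RD, EV_RD)) {   // premature drop
      unbind_rep(c, cx);
      return;
    }
    // the bound REP itself risks chain breaking
    int bonds = (int)cx.rep.seq.size() - 1;
    ll k = binom(bonds, P.P_BB);
    if (k > 0) {
      int cut = 1 + randint(bonds);  // break after position cut-1
      Seq left(cx.rep.seq.begin(), cx.rep.seq.begin() + cut);
      Seq right(cx.rep.seq.begin() + cut, cx.rep.seq.end());
      comp_add_strand(c, left);
      comp_add_strand(c, right);
      cx.has_rep = false;
      cx.rep = Strand();
      product_to_sub(cx);
    }
  }

  void unbind_rep(Comp c, Complex& cx) {
    comp_add_strand(c, cx.rep.seq);
    cx.has_rep = false;
    cx.rep = Strand();
    cx.recognition_paired = false;
    product_to_sub(cx);
  }

  void product_to_sub(Complex& cx) {
    if (!cx.product.empty()) {
      Aligned a;
      a.off = (int)cx.tpl.seq.size() - cx.copied;
      a.seq = cx.product;
      cx.subs.push_back(std::move(a));
      std::sort(cx.subs.begin(), cx.subs.end(),
                [](const Aligned& x, const Aligned& y) {
                  return x.off < y.off;
                });
    }
    cx.product.clear();
    cx.prod_mm.clear();
    cx.copied = 0;
  }

  void template_ligation(Comp c, Complex& cx) {
    const Pars& P = *c.P;
    bool merged = true;
    while (merged) {
      merged = false;
      for (size_t i = 0; i + 1 < cx.subs.size(); ++i) {
        Aligned& lo = cx.subs[i];
        Aligned& hi = cx.subs[i + 1];
        if (lo.off + (int)lo.seq.size() == hi.off &&
            bern(P.P_TL, EV_TL)) {
          // hi covers higher template positions = 5' part of the product
          Seq joined = hi.seq;
          joined.insert(joined.end(), lo.seq.begin(), lo.seq.end());
          lo.seq = std::move(joined);
          cx.subs.erase(cx.subs.begin() + i + 1);
          merged = true;
          break;
        }
      }
    }
  }

  void separations(Comp c, Complex& cx) {
    const Pars& P = *c.P;
    std::vector<int> gone;
    for (int i = 0; i < (int)cx.subs.size(); ++i) {
      int r = (int)cx.subs[i].seq.size();
      if (bern(f_separation(r, P.P_SP), EV_SEP)) {
        comp_add_strand(c, cx.subs[i].seq);
        gone.push_back(i);
      }
    }
    drop_indices(cx.subs, gone);
  }

  void bond_breaking(Comp c) {
    const Pars& P = *c.P;
    std::vector<Strand>& ss = *c.strands;
    std::vector<int> rm_s;
    int n_str = (int)ss.size();
    for (int i = 0; i < n_str; ++i) {
      int bonds = (int)ss[i].seq.size() - 1;
      if (bonds <= 0) continue;
      ll k = binom(bonds, P.P_BB);
      if (k > 0) {
        int cut = 1 + randint(bonds);
        Seq left(ss[i].seq.begin(), ss[i].seq.begin() + cut);
        Seq right(ss[i].seq.begin() + cut, ss[i].seq.end());
        rm_s.push_back(i);
        comp_add_strand(c, left);
        comp_add_strand(c, right);
      }
    }
    drop_indices(ss, rm_s);
    // complexes: a break in the double-chain region severs both parallel
    // bonds at once (P_BB^(3/2)); a break anywhere dissolves the complex
    // into its member strands (the fragments drop from the template)
    std::vector<Complex>& cc = *c.cxs;
    std::vector<int> rm_c;
    for (int ci = 0; ci < (int)cc.size(); ++ci) {
      Complex& cx = cc[ci];
      const std::vector<uint8_t>& cov = coverage(cx);
      int nb = (int)cx.tpl.seq.size() - 1;
      bool broke = false;
      int cut = -1;
      bool dbl = false;
      for (int q = 0; q < nb && !broke; ++q) {
        bool d = cov[q] && cov[q + 1];
        if (bern(f_bond_break(d, P.P_BB))) { broke = true; cut = q + 1; dbl = d; }
      }
      if (!broke) continue;
      // release everything; split the template (and, for a double-chain
      // break, the covering partner at the corresponding bond)
      if (cx.has_rep) comp_add_strand(c, cx.rep.seq);
      if (!cx.product.empty()) comp_add_strand(c, cx.product);
      Seq tl(cx.tpl.seq.begin(), cx.tpl.seq.begin() + cut);
      Seq tr(cx.tpl.seq.begin() + cut, cx.tpl.seq.end());
      comp_add_strand(c, tl);
      comp_add_strand(c, tr);
      for (Aligned& a : cx.subs) {
        int L = (int)a.seq.size();
        if (dbl && a.off < cut && cut < a.off + L) {
          int j = a.off + L - cut;  // partner bond matching template bond
          Seq p1(a.seq.begin(), a.seq.begin() + j);
          Seq p2(a.seq.begin() + j, a.seq.end());
          comp_add_strand(c, p1);
          comp_add_strand(c, p2);
        } else {
          comp_add_strand(c, a.seq);
        }
      }
      rm_c.push_back(ci);
    }
    drop_indices(cc, rm_c);
  }

  void end_decay(Comp c) {
    const Pars& P = *c.P;
    std::vector<Strand>& ss = *c.strands;
    std::vector<int> rm_s;
    for (int i = 0; i < (int)ss.size(); ++i) {
      Seq& s = ss[i].seq;
      bool d5 = bern(P.P_NDE, EV_NDE);
      bool d3 = bern(P.P_NDE, EV_NDE);
      if (!d5 && !d3) continue;
      int lost = (d5 ? 1 : 0) + (d3 ? 1 : 0);
      if ((int)s.size() <= lost) {
        // the strand vanishes entirely into precursors
        c.pools->np += (ll)s.size();
        if (c.cell) c.cell->n_cache -= (ll)s.size();
        rm_s.push_back(i);
        continue;
      }
      Seq trimmed(s.begin() + (d5 ? 1 : 0), s.end() - (d3 ? 1 : 0));
      c.pools->np += lost;
      if (c.cell) c.cell->n_cache -= lost;
      if (trimmed.size() == 1) {
        c.pools->nt[trimmed[0]]++;
        rm_s.push_back(i);
      } else {
        ss[i].seq = std::move(trimmed);
        ss[i].flags = classify_seq(ss[i].seq, cs);
        ss[i].tstate = 0;
      }
    }
    drop_indices(ss, rm_s);
    // template ends decay only when unpaired
    for (Complex& cx : *c.cxs) {
      const std::vector<uint8_t>& cov = coverage(cx);
      int n = (int)cx.tpl.seq.size();
      if (n <= 1) continue;
      bool d5 = !cov[0] && bern(P.P_NDE, EV_NDE);
      bool d3 = !cov[n - 1] && bern(P.P_NDE, EV_NDE);
      if (!d5 && !d3) continue;
      Seq& t = cx.tpl.seq;
      int lost = (d5 ? 1 : 0) + (d3 ? 1 : 0);
      Seq trimmed(t.begin() + (d5 ? 1 : 0), t.end() - (d3 ? 1 : 0));
      c.pools->np += lost;
      if (c.cell) c.cell->n_cache -= lost;
      cx.tpl.seq = std::move(trimmed);
      cx.tpl.flags = classify_seq(cx.tpl.seq, cs);
      if (d5)
        for (Aligned& a : cx.subs) a.off -= 1;
    }
  }

  // ===================================================== protocell events
  void phase_protocell(std::vector<int>& order) {
    for (int i : order) {
      Room& rm = rooms[i];
      if (rm.cell) {
        membrane_decay(i);
        if (!rm.cell) continue;
        membrane_join(i);
        amphiphile_leave(i);
        if (!rm.cell) continue;
        if (bern(base.P_CB, EV_CB)) { dissolve_cell(i); continue; }
        division(i);
        fusion(i);
        if (!rm.cell) continue;
        if (bern(base.P_CC, EV_CC)) cytophagy(i);
        permeation(i);
      } else {
        membrane_formation(i);
      }
    }
  }

  void membrane_join(int i) {
    Cell& cell = *rooms[i].cell;
    // interior free amphiphiles join from within
    ll k = binom(cell.pools.am, base.P_AJM, EV_AJM);
    cell.pools.am -= k;
    cell.b += k;
    // exterior amphiphiles join through the face toward their room
    for (int d = 0; d < 4; ++d) {
      Room& nb = rooms[this->nbr[i][d]];
      if (nb.cell) continue;
      ll kj = binom(nb.pools.am, base.P_AJM / 4.0);
      nb.pools.am -= kj;
      cell.b += kj;
    }
  }

  void amphiphile_leave(int i) {
    Cell& cell = *rooms[i].cell;
    double p = f_leave(cell.b, cell.n_cache, base.P_ALM, base.F_OP);
    ll k = binom(cell.b, p);
    if (k <= 0) return;
    cell.b -= k;
    std::vector<int> tgt = open_neighbors(i);
    if (tgt.empty()) cell.pools.am += k;
    else
      for (ll j = 0; j < k; ++j)
        rooms[tgt[randint((int)tgt.size())]].pools.am++;
    if (cell.b <= 0) dissolve_cell(i);
  }

  void dissolve_cell(int i) {
    Room& rm = rooms[i];
    Cell& cell = *rm.cell;
    rm.pools.np += cell.pools.np;
    for (int l = 0; l < 4; ++l) rm.pools.nt[l] += cell.pools.nt[l];
    rm.pools.ap += cell.pools.ap;
    rm.pools.am += cell.pools.am + cell.b;
    for (Strand& s : cell.strands) rm.strands.push_back(std::move(s));
    for (Complex& cx : cell.cxs) rm.cxs.push_back(std::move(cx));
    rm.cell.reset();
  }

  void membrane_formation(int i) {
    Room& rm = rooms[i];
    if (!prof[rm.region].protocells_allowed) return;
    double p = f_membrane(rm.pools.am, base.P_MF, base.L_AM);
    if (p <= 0 || !bern(p)) return;
    auto cell = std::unique_ptr<Cell>(new Cell());
    cell->b = rm.pools.am;
    rm.pools.am = 0;
    cell->pools = rm.pools;
    rm.pools = Pools();
    cell->strands = std::move(rm.strands);
    rm.strands.clear();
    cell->cxs = std::move(rm.cxs);
    rm.cxs.clear();
    cell->n_cache = cell_n_recompute(*cell);
    rm.cell = std::move(cell);
  }

  void division(int i) {
    Room& rm = rooms[i];
    Cell& cell = *rm.cell;
    double p = f_division(cell.b, base.P_CD, base.L_AM);
    if (p <= 0) { ev_att[EV_CD]++; return; }
    if (!bern(p, EV_CD)) return;
    std::vector<int> cand;
    for (int d = 0; d < 4; ++d) {
      int t = this->nbr[i][d];
      if (!rooms[t].cell && prof[rooms[t].region].protocells_allowed)
        cand.push_back(t);
    }
    if (cand.empty()) return;
    int t = cand[randint((int)cand.size())];
    // displace the target room's free content to its other open neighbours
    std::vector<int> spill;
    for (int d = 0; d < 4; ++d) {
      int u = this->nbr[t][d];
      if (u != i && !rooms[u].cell) spill.push_back(u);
    }
    if (spill.empty()) return;  // nowhere to push: division aborts
    Room& tr = rooms[t];
    scatter_room_contents(tr, spill);
    // split the membrane as evenly as possible
    auto daughter = std::unique_ptr<Cell>(new Cell());
    ll b1 = cell.b / 2;
    daughter->b = cell.b - b1;
    cell.b = b1;
    // interior molecules partition independently
    ll mv = binom(cell.pools.np, 0.5);
    cell.pools.np -= mv; daughter->pools.np += mv;
    for (int l = 0; l < 4; ++l) {
      mv = binom(cell.pools.nt[l], 0.5);
      cell.pools.nt[l] -= mv; daughter->pools.nt[l] += mv;
    }
    mv = binom(cell.pools.ap, 0.5);
    cell.pools.ap -= mv; daughter->pools.ap += mv;
    mv = binom(cell.pools.am, 0.5);
    cell.pools.am -= mv; daughter->pools.am += mv;
    std::vector<Strand> keep_s;
    for (Strand& s : cell.strands) {
      if (bern(0.5)) daughter->strands.push_back(std::move(s));
      else keep_s.push_back(std::move(s));
    }
    cell.strands = std::move(keep_s);
    std::vector<Complex> keep_c;
    for (Complex& cx : cell.cxs) {
      if (bern(0.5)) daughter->cxs.push_back(std::move(cx));
      else keep_c.push_back(std::move(cx));
    }
    cell.cxs = std::move(keep_c);
    cell.n_cache = cell_n_recompute(cell);
    daughter->n_cache = cell_n_recompute(*daughter);
    tr.cell = std::move(daughter);
  }

  void scatter_room_contents(Room& tr, const std::vector<int>& spill) {
    auto scatter_count = [&](ll cnt, int what, int letter) {
      for (ll q = 0; q < cnt; ++q) {
        Room& u = rooms[spill[randint((int)spill.size())]];
        if (what == 0) u.pools.np++;
        else if (what == 1) u.pools.nt[letter]++;
        else if (what == 2) u.pools.ap++;
        else u.pools.am++;
      }
    };
    scatter_count(tr.pools.np, 0, 0);
    for (int l = 0; l < 4; ++l) scatter_count(tr.pools.nt[l], 1, l);
    scatter_count(tr.pools.ap, 2, 0);
    scatter_count(tr.pools.am, 3, 0);
    tr.pools = Pools();
    for (Strand& s : tr.strands)
      rooms[spill[randint((int)spill.size())]].strands.push_back(
          std::move(s));
    tr.strands.clear();
    for (Complex& cx : tr.cxs)
      rooms[spill[randint((int)spill.size())]].cxs.push_back(std::move(cx));
    tr.cxs.clear();
  }

  void fusion(int i) {
    Room& rm = rooms[i];
    if (!rm.cell) return;
    // check right and down only, so each adjacent pair is tried once
    for (int d = 0; d < 4; d += 2) {
      int t = this->nbr[i][d];
      if (t == i || !rooms[t].cell) continue;
      if (!rm.cell) return;
      if (!bern(base.P_CF, EV_CF)) continue;
      int big = rooms[t].cell->b > rm.cell->b ? t : i;
      if (rooms[t].cell->b == rm.cell->b && bern(0.5)) big = t;
      int small = big == t ? i : t;
      Cell& cb = *rooms[big].cell;
      Cell& csml = *rooms[small].cell;
      cb.b += csml.b;
      cb.pools.np += csml.pools.np;
      for (int l = 0; l < 4; ++l) cb.pools.nt[l] += csml.pools.nt[l];
      cb.pools.ap += csml.pools.ap;
      cb.pools.am += csml.pools.am;
      for (Strand& s : csml.strands) cb.strands.push_back(std::move(s));
      for (Complex& cx : csml.cxs) cb.cxs.push_back(std::move(cx));
      cb.n_cache += csml.n_cache;
      rooms[small].cell.reset();
      if (small == i) return;
    }
  }

  void cytophagy(int i) {
    Cell& cell = *rooms[i].cell;
    int t = this->nbr[i][randint(4)];
    Room& tr = rooms[t];
    if (tr.cell) return;
    cell.pools.np += tr.pools.np;
    ll gained = 0;
    for (int l = 0; l < 4; ++l) {
      cell.pools.nt[l] += tr.pools.nt[l];
      gained += tr.pools.nt[l];
    }
    cell.pools.ap += tr.pools.ap;
    cell.pools.am += tr.pools.am;
    tr.pools = Pools();
    gained += compartment_residues(tr.strands, tr.cxs);
    for (Strand& s : tr.strands) cell.strands.push_back(std::move(s));
    tr.strands.clear();
    for (Complex& cx : tr.cxs) cell.cxs.push_back(std::move(cx));
    tr.cxs.clear();
    cell.n_cache += gained;
  }

  void permeation(int i) {
    Cell& cell = *rooms[i].cell;
    // outward first (flat rates, leaver exits through a random open face),
    // so material arriving this step is not flushed straight back out and
    // the interior holds its equilibrium level even at permeability 1
    std::vector<int> tgt = open_neighbors(i);
    if (!tgt.empty()) {
      ll ko = binom(cell.pools.np, clamp01(base.P_NPP));
      cell.pools.np -= ko;
      for (ll q = 0; q < ko; ++q)
        rooms[tgt[randint((int)tgt.size())]].pools.np++;
      ll ka = binom(cell.pools.ap, clamp01(base.P_APP));
      cell.pools.ap -= ka;
      for (ll q = 0; q < ka; ++q)
        rooms[tgt[randint((int)tgt.size())]].pools.ap++;
    }
    // inward: each neighbouring room's precursors cross through one of the
    // four membrane faces
    double pin = f_perm_in(cell.b, cell.n_cache, base.P_NPP, base.L_AM,
                           base.F_DE);
    for (int d = 0; d < 4; ++d) {
      Room& nb = rooms[this->nbr[i][d]];
      if (nb.cell) continue;
      ll k = binom(nb.pools.np, pin / 4.0);
      nb.pools.np -= k;
      cell.pools.np += k;
      ll ka = binom(nb.pools.ap, clamp01(base.P_APP) / 4.0);
      nb.pools.ap -= ka;
      cell.pools.ap += ka;
    }
  }

  // ============================================================ movement
  bool may_cross(uint8_t from_region, uint8_t to_region, int cls) {
    // cls: 0 np, 1 nt, 2 ap, 3 am, 4 strand
    if (from_region == to_region) return true;
    if (interface_policy == 1) return true;
    return cls == 0 || cls == 2;  // raw materials only
  }

  void phase_movement() {
    int NN = N * N;
    // stage incoming movers so nothing gets a second trial within the step
    std::vector<Pools> in_pools(NN);
    std::vector<std::vector<Strand> > in_strands(NN);
    std::vector<std::vector<Complex> > in_cxs(NN);
    for (int i = 0; i < NN; ++i) {
      Room& rm = rooms[i];
      if (rm.cell) continue;
      const Pars& P = eff[rm.region][0];
      EvId mvid = rm.region == 0 ? EV_MV_R0 : EV_MV_R1;
      // pools: draw movers per class (nucleotide letters attributed after
      // the aggregate draw)
      ll counts[4] = {rm.pools.np, rm.pools.nt_total(), rm.pools.ap,
                      rm.pools.am};
      int clsmap[4] = {0, 1, 2, 3};
      for (int w = 0; w < 4; ++w) {
        if (counts[w] <= 0) continue;
        ll movers = binom(counts[w], P.P_MV, mvid);
        for (ll q = 0; q < movers; ++q) {
          int letter = -1;
          if (w == 1) {
            letter = draw_letter(rm.pools.nt, rm.pools.nt_total());
          }
          int t = this->nbr[i][randint(4)];
          Room& tr = rooms[t];
          if (tr.cell) continue;  // membrane blocks; permeation is separate
          if (!may_cross(rm.region, tr.region, clsmap[w])) continue;
          switch (w) {
            case 0: rm.pools.np--; in_pools[t].np++; break;
            case 1: rm.pools.nt[letter]--; in_pools[t].nt[letter]++; break;
            case 2: rm.pools.ap--; in_pools[t].ap++; break;
            case 3: rm.pools.am--; in_pools[t].am++; break;
          }
        }
      }
      // free strands; a template complex moves as one unit with the summed
      // mass of its member chains (hybridized strands never move alone)
      std::vector<int> moved;
      for (int si = 0; si < (int)rm.strands.size(); ++si) {
        double p = f_move((int)rm.strands[si].seq.size(), P.P_MV);
        if (!bern(p)) continue;
        int t = this->nbr[i][randint(4)];
        Room& tr = rooms[t];
        if (tr.cell) continue;
        if (!may_cross(rm.region, tr.region, 4)) continue;
        in_strands[t].push_back(std::move(rm.strands[si]));
        moved.push_back(si);
      }
      drop_indices(rm.strands, moved);
      std::vector<int> moved_cx;
      for (int ci = 0; ci < (int)rm.cxs.size(); ++ci) {
        double p = f_move((int)complex_residues(rm.cxs[ci]), P.P_MV);
        if (!bern(p)) continue;
        int t = this->nbr[i][randint(4)];
        Room& tr = rooms[t];
        if (tr.cell) continue;
        if (!may_cross(rm.region, tr.region, 4)) continue;
        in_cxs[t].push_back(std::move(rm.cxs[ci]));
        moved_cx.push_back(ci);
      }
      drop_indices(rm.cxs, moved_cx);
    }
    for (int i = 0; i < NN; ++i) {
      Room& rm = rooms[i];
      rm.pools.np += in_pools[i].np;
      for (int l = 0; l < 4; ++l) rm.pools.nt[l] += in_pools[i].nt[l];
      rm.pools.ap += in_pools[i].ap;
      rm.pools.am += in_pools[i].am;
      for (Strand& s : in_strands[i]) rm.strands.push_back(std::move(s));
      for (Complex& cx : in_cxs[i]) rm.cxs.push_back(std::move(cx));
    }
    // protocells move after molecules
    std::vector<int> cell_rooms;
    for (int i = 0; i < NN; ++i)
      if (rooms[i].cell) cell_rooms.push_back(i);
    for (int i : cell_rooms) {
      if (!rooms[i].cell) continue;  // may have fused/moved already
      if (!bern(base.P_MC, EV_MC)) continue;
      std::vector<int> cand;
      for (int d = 0; d < 4; ++d) {
        int t = this->nbr[i][d];
        if (!rooms[t].cell && prof[rooms[t].region].protocells_allowed)
          cand.push_back(t);
      }
      if (cand.empty()) continue;
      int t = cand[randint((int)cand.size())];
      Room& from = rooms[i];
      Room& to = rooms[t];
      // swap: the cell moves in, the target's free content is pushed into
      // the vacated room
      from.cell.swap(to.cell);
      std::swap(from.pools, to.pools);
      from.strands.swap(to.strands);
      from.cxs.swap(to.cxs);
    }
  }

  // ================================================================= step
  void step() {
    using clk = std::chrono::steady_clock;
    int NN = N * N;
    std::vector<int> order(NN);
    for (int i = 0; i < NN; ++i) order[i] = i;
    for (int i = NN - 1; i > 0; --i) std::swap(order[i], order[randint(i + 1)]);

    auto t0 = clk::now();
    // (1) chemistry
    for (int i : order) {
      if (rooms[i].cell) phase_chemistry(cell_comp(i));
      else phase_chemistry(room_comp(i));
    }
    auto t1 = clk::now();
    // (2) collision rounds (compartments are independent within the phase)
    for (int i : order) {
      if (rooms[i].cell) collision_rounds(cell_comp(i), base.C_T);
      else collision_rounds(room_comp(i), base.C_T);
    }
    auto t2 = clk::now();
    // (3) polymer events
    for (int i : order) {
      if (rooms[i].cell) phase_polymer(cell_comp(i));
      else phase_polymer(room_comp(i));
    }
    auto t3 = clk::now();
    // (4) membrane / protocell events
    phase_protocell(order);
    auto t4 = clk::now();
    // (5) movement: molecules, then protocells (interface rules enforced
    //     inside the movement step)
    phase_movement();
    auto t5 = clk::now();
    phase_ns[0] += std::chrono::duration<double, std::nano>(t1 - t0).count();
    phase_ns[1] += std::chrono::duration<double, std::nano>(t2 - t1).count();
    phase_ns[2] += std::chrono::duration<double, std::nano>(t3 - t2).count();
    phase_ns[3] += std::chrono::duration<double, std::nano>(t4 - t3).count();
    phase_ns[4] += std::chrono::duration<double, std::nano>(t5 - t4).count();
    step_count++;
    if (ledger_every > 0 && step_count % ledger_every == 0) check_ledgers();
  }

  // ============================================================ observers
  void count_strand(uint32_t flags, bool in_cell, uint8_t region,
                    std::vector<ll>& v) {
    // v: rep_naked nsr_naked para_naked rep_cell nsr_cell para_cell
    //    rep_rocky nsr_rocky rep_species nsr_species
    if (flags & RF_REP) { v[in_cell ? 3 : 0]++; if (!in_cell && region == 0) v[6]++; }
    if (flags & RF_NSR) { v[in_cell ? 4 : 1]++; if (!in_cell && region == 0) v[7]++; }
    if (flags & RF_PARA) v[in_cell ? 5 : 2]++;
    if (flags & RF_REP_DOM) v[8]++;
    if (flags & RF_NSR_DOM) v[9]++;
  }

  NumericVector counts() {
    ll np = 0, nt = 0, ap = 0, am = 0, strands = 0, cells = 0;
    ll np_rocky = 0, np_sol = 0;
    std::vector<ll> role(10, 0);
    for (const Room& rm : rooms) {
      const Pools* pls[2] = {&rm.pools, rm.cell ? &rm.cell->pools : nullptr};
      for (int w = 0; w < 2; ++w) {
        if (!pls[w]) continue;
        np += pls[w]->np;
        nt += pls[w]->nt_total();
        ap += pls[w]->ap;
        am += pls[w]->am;
        if (rm.region == 0) np_rocky += pls[w]->np;
        else np_sol += pls[w]->np;
      }
      if (rm.cell) cells++;
      auto count_comp = [&](const std::vector<Strand>& ss,
                            const std::vector<Complex>& cc, bool in_cell) {
        for (const Strand& s : ss) {
          strands++;
          count_strand(s.flags, in_cell, rm.region, role);
        }
        for (const Complex& cx : cc) {
          strands += 1 + (ll)cx.subs.size() + (cx.has_rep ? 1 : 0);
          count_strand(cx.tpl.flags, in_cell, rm.region, role);
          for (const Aligned& a : cx.subs)
            count_strand(classify_seq(a.seq, cs), in_cell, rm.region, role);
          if (cx.has_rep)
            count_strand(cx.rep.flags, in_cell, rm.region, role);
        }
      };
      count_comp(rm.strands, rm.cxs, false);
      if (rm.cell) count_comp(rm.cell->strands, rm.cell->cxs, true);
    }
    NumericVector out = NumericVector::create(
        _["step"] = (double)step_count, _["np"] = (double)np,
        _["nt"] = (double)nt, _["ap"] = (double)ap, _["am"] = (double)am,
        _["strands"] = (double)strands, _["rep_naked"] = (double)role[0],
        _["nsr_naked"] = (double)role[1], _["para_naked"] = (double)role[2],
        _["rep_cell"] = (double)role[3], _["nsr_cell"] = (double)role[4],
        _["para_cell"] = (double)role[5], _["cells"] = (double)cells,
        _["np_rocky"] = (double)np_rocky, _["np_solution"] = (double)np_sol,
        _["rep_rocky"] = (double)role[6], _["nsr_rocky"] = (double)role[7],
        _["rep_species"] = (double)role[8],
        _["nsr_species"] = (double)role[9]);
    return out;
  }
};

// ------------------------------------------------------------ R interface

static Pars pars_from_list(const List& p) {
  Pars P;
  P.P_AT = p["P_AT"]; P.P_BB = p["P_BB"]; P.P_FLR = p["P_FLR"];
  P.P_FP = p["P_FP"]; P.P_MV = p["P_MV"]; P.P_ND = p["P_ND"];
  P.P_NDE = p["P_NDE"]; P.P_NF = p["P_NF"]; P.P_NFR = p["P_NFR"];
  P.P_RBT = p["P_RBT"]; P.P_RD = p["P_RD"]; P.P_RL = p["P_RL"];
  P.P_RTT = p["P_RTT"]; P.P_SP = p["P_SP"]; P.P_TL = p["P_TL"];
  P.P_TLR = p["P_TLR"]; P.P_AD = p["P_AD"]; P.P_ADM = p["P_ADM"];
  P.P_AF = p["P_AF"]; P.P_AJM = p["P_AJM"]; P.P_ALM = p["P_ALM"];
  P.P_APP = p["P_APP"]; P.P_CB = p["P_CB"]; P.P_CC = p["P_CC"];
  P.P_CD = p["P_CD"]; P.P_CF = p["P_CF"]; P.P_MC = p["P_MC"];
  P.P_MF = p["P_MF"]; P.P_NPP = p["P_NPP"];
  P.F_OP = p["F_OP"]; P.F_DE = p["F_DE"];
  P.N = as<int>(p["N"]); P.C_T = as<int>(p["C_T"]);
  P.L_AM = as<int>(p["L_AM"]);
  P.T_NPB = (ll)as<double>(p["T_NPB"]);
  P.T_APB = (ll)as<double>(p["T_APB"]);
  return P;
}

// [[Rcpp::export]]
SEXP cpp_sim_new(List params, IntegerVector region, List profiles,
                 int interface_policy, double seed, int N) {
  Sim* sim = new Sim();
  sim->base = pars_from_list(params);
  sim->N = N;
  sim->interface_policy = interface_policy;
  std::string tag = as<std::string>(params["CS_Tag"]);
  std::string rep = as<std::string>(params["CS_REP"]);
  std::string nsr = as<std::string>(params["CS_NSR"]);
  sim->cs.tag = encode_seq(tag);
  sim->cs.rep = encode_seq(rep);
  sim->cs.nsr = encode_seq(nsr);
  sim->cs.rep_rc = revcomp(sim->cs.rep);
  sim->cs.nsr_rc = revcomp(sim->cs.nsr);
  sim->cs.tag_rep = sim->cs.tag;
  sim->cs.tag_rep.insert(sim->cs.tag_rep.end(), sim->cs.rep.begin(),
                         sim->cs.rep.end());
  if (revcomp(sim->cs.tag) != sim->cs.tag) {
    delete sim;
    stop("tag not palindromic");
  }
  for (int r = 0; r < 2; ++r) {
    List pr = profiles[r];
    sim->prof[r].mv_mult = pr["mv_mult"];
    sim->prof[r].degr_mult = pr["degr_mult"];
    sim->prof[r].syn_mult = pr["syn_mult"];
    sim->prof[r].protocells_allowed = pr["protocells_allowed"];
  }
  sim->rebuild_eff();
  sim->build_grid(region);
  sim->rng.seed((uint64_t)seed);
  XPtr<Sim> xp(sim, true);
  return xp;
}

// [[Rcpp::export]]
void cpp_set_param(SEXP xp_, std::string name, double value) {
  XPtr<Sim> xp(xp_);
  Pars& P = xp->base;
  if (name == "P_AT") P.P_AT = value;
  else if (name == "P_BB") P.P_BB = value;
  else if (name == "P_FLR") P.P_FLR = value;
  else if (name == "P_FP") P.P_FP = value;
  else if (name == "P_MV") P.P_MV = value;
  else if (name == "P_ND") P.P_ND = value;
  else if (name == "P_NDE") P.P_NDE = value;
  else if (name == "P_NF") P.P_NF = value;
  else if (name == "P_NFR") P.P_NFR = value;
  else if (name == "P_RBT") P.P_RBT = value;
  else if (name == "P_RD") P.P_RD = value;
  else if (name == "P_RL") P.P_RL = value;
  else if (name == "P_RTT") P.P_RTT = value;
  else if (name == "P_SP") P.P_SP = value;
  else if (name == "P_TL") P.P_TL = value;
  else if (name == "P_TLR") P.P_TLR = value;
  else if (name == "P_AD") P.P_AD = value;
  else if (name == "P_ADM") P.P_ADM = value;
  else if (name == "P_AF") P.P_AF = value;
  else if (name == "P_AJM") P.P_AJM = value;
  else if (name == "P_ALM") P.P_ALM = value;
  else if (name == "P_APP") P.P_APP = value;
  else if (name == "P_CB") P.P_CB = value;
  else if (name == "P_CC") P.P_CC = value;
  else if (name == "P_CD") P.P_CD = value;
  else if (name == "P_CF") P.P_CF = value;
  else if (name == "P_MC") P.P_MC = value;
  else if (name == "P_MF") P.P_MF = value;
  else if (name == "P_NPP") P.P_NPP = value;
  else if (name == "C_T") P.C_T = (int)value;
  else if (name == "L_AM") P.L_AM = (int)value;
  else if (name == "F_OP") P.F_OP = value;
  else if (name == "F_DE") P.F_DE = value;
  else stop("unknown or immutable parameter '%s'", name);
  xp->rebuild_eff();
}

// [[Rcpp::export]]
void cpp_seed_pools(SEXP xp_, NumericVector np, NumericVector ap) {
  XPtr<Sim> xp(xp_);
  if ((int)np.size() != xp->N * xp->N || (int)ap.size() != xp->N * xp->N)
    stop("pool vectors must have N*N entries");
  for (int i = 0; i < xp->N * xp->N; ++i) {
    xp->rooms[i].pools.np += (ll)np[i];
    xp->rooms[i].pools.ap += (ll)ap[i];
    xp->nt_expected += (ll)np[i];
    xp->am_expected += (ll)ap[i];
  }
}

// restore per-room pools from a snapshot; nucleotide letter identity is not
// part of the snapshot, so nt totals are split as evenly as possible
// [[Rcpp::export]]
void cpp_restore_pools(SEXP xp_, NumericVector np, NumericVector nt,
                       NumericVector ap, NumericVector am) {
  XPtr<Sim> xp(xp_);
  int NN = xp->N * xp->N;
  if ((int)np.size() != NN) stop("pool vectors must have N*N entries");
  for (int i = 0; i < NN; ++i) {
    Room& rm = xp->rooms[i];
    rm.pools.np += (ll)np[i];
    ll tot = (ll)nt[i];
    for (int l = 0; l < 4; ++l) rm.pools.nt[l] += tot / 4 + (l < tot % 4);
    rm.pools.ap += (ll)ap[i];
    rm.pools.am += (ll)am[i];
    xp->nt_expected += (ll)np[i] + tot;
    xp->am_expected += (ll)ap[i] + (ll)am[i];
  }
}

// [[Rcpp::export]]
void cpp_add_strands(SEXP xp_, IntegerVector rooms, CharacterVector seqs,
                     bool interior) {
  XPtr<Sim> xp(xp_);
  for (int i = 0; i < rooms.size(); ++i) {
    int r = rooms[i];
    if (r < 0 || r >= xp->N * xp->N) stop("room index out of range");
    Seq s = encode_seq(as<std::string>(seqs[i]));
    xp->nt_expected += (ll)s.size();
    if (interior) {
      if (!xp->rooms[r].cell) stop("room %d holds no protocell", r);
      xp->rooms[r].cell->n_cache += (ll)s.size();
      Sim::add_strand(xp->rooms[r].cell->pools, xp->rooms[r].cell->strands,
                      std::move(s), xp->cs);
    } else {
      Sim::add_strand(xp->rooms[r].pools, xp->rooms[r].strands,
                      std::move(s), xp->cs);
    }
  }
}

// [[Rcpp::export]]
void cpp_add_cell(SEXP xp_, int room, double b, CharacterVector seqs,
                  double np, double ap, double nt_total, double am) {
  XPtr<Sim> xp(xp_);
  if (room < 0 || room >= xp->N * xp->N) stop("room index out of range");
  Room& rm = xp->rooms[room];
  if (rm.cell) stop("room %d already holds a protocell", room);
  // push the room's current free content aside before the cell moves in
  std::vector<int> spill = xp->open_neighbors(room);
  if (!spill.empty()) xp->scatter_room_contents(rm, spill);
  auto cell = std::unique_ptr<Cell>(new Cell());
  cell->b = (ll)b;
  cell->pools.np = (ll)np;
  cell->pools.ap = (ll)ap;
  ll tot = (ll)nt_total;
  for (int l = 0; l < 4; ++l) cell->pools.nt[l] = tot / 4 + (l < tot % 4);
  cell->pools.am = (ll)am;
  for (int i = 0; i < seqs.size(); ++i) {
    Seq s = encode_seq(as<std::string>(seqs[i]));
    xp->nt_expected += (ll)s.size();
    Sim::add_strand(cell->pools, cell->strands, std::move(s), xp->cs);
  }
  cell->n_cache = Sim::cell_n_recompute(*cell);
  xp->nt_expected += (ll)np + tot;
  xp->am_expected += (ll)b + (ll)ap + (ll)am;
  rm.cell = std::move(cell);
}

// [[Rcpp::export]]
NumericMatrix cpp_run(SEXP xp_, double steps, double sample_every) {
  XPtr<Sim> xp(xp_);
  ll K = (ll)steps, SE = (ll)sample_every;
  if (SE < 1) SE = 1;
  ll nrow = K / SE + 1;
  NumericVector c0 = xp->counts();
  NumericMatrix out((int)nrow, c0.size());
  CharacterVector cn = c0.names();
  colnames(out) = cn;
  int row = 0;
  for (int j = 0; j < c0.size(); ++j) out(row, j) = c0[j];
  row++;
  for (ll k = 1; k <= K; ++k) {
    xp->step();
    if (k % SE == 0 && row < (int)nrow) {
      NumericVector cc = xp->counts();
      for (int j = 0; j < cc.size(); ++j) out(row, j) = cc[j];
      row++;
    }
    if (k % 4096 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_counts(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  return xp->counts();
}

// [[Rcpp::export]]
double cpp_step_count(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  return (double)xp->step_count;
}

// [[Rcpp::export]]
NumericVector cpp_ledger(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  return NumericVector::create(
      _["nt_equivalents"] = (double)xp->nt_equivalents(),
      _["nt_expected"] = (double)(ll)xp->nt_expected,
      _["am_equivalents"] = (double)xp->am_equivalents(),
      _["am_expected"] = (double)(ll)xp->am_expected);
}

// [[Rcpp::export]]
void cpp_check_ledgers(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  xp->check_ledgers();
}

// [[Rcpp::export]]
void cpp_set_ledger_every(SEXP xp_, int every) {
  XPtr<Sim> xp(xp_);
  xp->ledger_every = every;
}

// [[Rcpp::export]]
DataFrame cpp_rooms(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  int NN = xp->N * xp->N;
  IntegerVector x(NN), y(NN);
  CharacterVector region(NN);
  NumericVector np(NN), nt(NN), ap(NN), am(NN), cell_b(NN), cell_np(NN),
      cell_nt(NN), cell_ap(NN), cell_am(NN), cell_n(NN);
  LogicalVector has_cell(NN);
  for (int i = 0; i < NN; ++i) {
    const Room& rm = xp->rooms[i];
    x[i] = i % xp->N;
    y[i] = i / xp->N;
    region[i] = rm.region == 0 ? "rocky" : "solution";
    np[i] = (double)rm.pools.np;
    nt[i] = (double)rm.pools.nt_total();
    ap[i] = (double)rm.pools.ap;
    am[i] = (double)rm.pools.am;
    has_cell[i] = rm.cell != nullptr;
    cell_b[i] = rm.cell ? (double)rm.cell->b : 0.0;
    cell_np[i] = rm.cell ? (double)rm.cell->pools.np : 0.0;
    cell_nt[i] = rm.cell ? (double)rm.cell->pools.nt_total() : 0.0;
    cell_ap[i] = rm.cell ? (double)rm.cell->pools.ap : 0.0;
    cell_am[i] = rm.cell ? (double)rm.cell->pools.am : 0.0;
    cell_n[i] = rm.cell ? (double)rm.cell->n_cache : 0.0;
  }
  return DataFrame::create(
      _["x"] = x, _["y"] = y, _["region"] = region, _["np"] = np,
      _["nt"] = nt, _["ap"] = ap, _["am"] = am, _["has_cell"] = has_cell,
      _["cell_b"] = cell_b, _["cell_np"] = cell_np, _["cell_nt"] = cell_nt,
      _["cell_ap"] = cell_ap, _["cell_am"] = cell_am, _["cell_n"] = cell_n);
}

// [[Rcpp::export]]
DataFrame cpp_strands(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  std::vector<int> room;
  std::vector<bool> in_cell;
  std::vector<std::string> seq, status;
  auto dump_comp = [&](int i, bool cellq, const std::vector<Strand>& ss,
                       const std::vector<Complex>& cc) {
    for (const Strand& s : ss) {
      room.push_back(i);
      in_cell.push_back(cellq);
      seq.push_back(decode_seq(s.seq));
      status.push_back("free");
    }
    for (const Complex& cx : cc) {
      room.push_back(i);
      in_cell.push_back(cellq);
      seq.push_back(decode_seq(cx.tpl.seq));
      status.push_back("template");
      for (const Aligned& a : cx.subs) {
        room.push_back(i);
        in_cell.push_back(cellq);
        seq.push_back(decode_seq(a.seq));
        status.push_back("substrate");
      }
      if (cx.has_rep) {
        room.push_back(i);
        in_cell.push_back(cellq);
        seq.push_back(decode_seq(cx.rep.seq));
        status.push_back("bound_rep");
      }
      if (!cx.product.empty()) {
        room.push_back(i);
        in_cell.push_back(cellq);
        seq.push_back(decode_seq(cx.product));
        status.push_back("product");
      }
    }
  };
  for (int i = 0; i < xp->N * xp->N; ++i) {
    const Room& rm = xp->rooms[i];
    dump_comp(i, false, rm.strands, rm.cxs);
    if (rm.cell) dump_comp(i, true, rm.cell->strands, rm.cell->cxs);
  }
  return DataFrame::create(_["room"] = wrap(room),
                           _["in_cell"] = wrap(in_cell),
                           _["seq"] = wrap(seq), _["status"] = wrap(status),
                           _["stringsAsFactors"] = false);
}

// one row per aligned partner (substrates, growing products, bound REPs)
// of every template complex, for debugging dumps
// [[Rcpp::export]]
DataFrame cpp_complexes(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  std::vector<int> room, off, cxid;
  std::vector<bool> in_cell;
  std::vector<std::string> tpl, partner, kind;
  int id = 0;
  auto dump = [&](int i, bool cellq, const std::vector<Complex>& cc) {
    for (const Complex& cx : cc) {
      std::string t = decode_seq(cx.tpl.seq);
      for (const Aligned& a : cx.subs) {
        room.push_back(i); in_cell.push_back(cellq); cxid.push_back(id);
        tpl.push_back(t); partner.push_back(decode_seq(a.seq));
        off.push_back(a.off); kind.push_back("substrate");
      }
      if (!cx.product.empty()) {
        room.push_back(i); in_cell.push_back(cellq); cxid.push_back(id);
        tpl.push_back(t); partner.push_back(decode_seq(cx.product));
        off.push_back((int)cx.tpl.seq.size() - cx.copied);
        kind.push_back("product");
      }
      if (cx.has_rep) {
        room.push_back(i); in_cell.push_back(cellq); cxid.push_back(id);
        tpl.push_back(t); partner.push_back(decode_seq(cx.rep.seq));
        off.push_back(0); kind.push_back("bound_rep");
      }
      if (cx.subs.empty() && cx.product.empty() && !cx.has_rep) {
        room.push_back(i); in_cell.push_back(cellq); cxid.push_back(id);
        tpl.push_back(t); partner.push_back("");
        off.push_back(0); kind.push_back("bare");
      }
      id++;
    }
  };
  for (int i = 0; i < xp->N * xp->N; ++i) {
    dump(i, false, xp->rooms[i].cxs);
    if (xp->rooms[i].cell) dump(i, true, xp->rooms[i].cell->cxs);
  }
  return DataFrame::create(_["complex"] = wrap(cxid), _["room"] = wrap(room),
                           _["in_cell"] = wrap(in_cell),
                           _["template"] = wrap(tpl),
                           _["partner"] = wrap(partner),
                           _["offset"] = wrap(off), _["kind"] = wrap(kind),
                           _["stringsAsFactors"] = false);
}

// [[Rcpp::export]]
NumericVector cpp_event_stats(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  NumericVector out(2 * EV_N_);
  CharacterVector nm(2 * EV_N_);
  for (int e = 0; e < EV_N_; ++e) {
    out[2 * e] = (double)xp->ev_att[e];
    out[2 * e + 1] = (double)xp->ev_suc[e];
    nm[2 * e] = std::string(EV_NAMES[e]) + ".attempts";
    nm[2 * e + 1] = std::string(EV_NAMES[e]) + ".successes";
  }
  out.names() = nm;
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_phase_times(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  NumericVector out = NumericVector::create(
      _["chemistry"] = xp->phase_ns[0], _["collisions"] = xp->phase_ns[1],
      _["polymer"] = xp->phase_ns[2], _["protocell"] = xp->phase_ns[3],
      _["movement"] = xp->phase_ns[4]);
  return out / 1e9;
}

// [[Rcpp::export]]
void cpp_reset_event_stats(SEXP xp_) {
  XPtr<Sim> xp(xp_);
  for (int e = 0; e < EV_N_; ++e) { xp->ev_att[e] = 0; xp->ev_suc[e] = 0; }
}

// engine-internal formula evaluators, exposed so tests can compare the
// compiled rules against the plain-R reference implementations
// [[Rcpp::export]]
NumericVector cpp_formula_separation(IntegerVector r, double psp) {
  NumericVector out(r.size());
  for (int i = 0; i < r.size(); ++i) out[i] = f_separation(r[i], psp);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_bond_break(LogicalVector dbl, double pbb) {
  NumericVector out(dbl.size());
  for (int i = 0; i < dbl.size(); ++i) out[i] = f_bond_break(dbl[i], pbb);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_membrane(NumericVector a, double pmf, int lam) {
  NumericVector out(a.size());
  for (int i = 0; i < a.size(); ++i) out[i] = f_membrane((ll)a[i], pmf, lam);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_leave(NumericVector b, NumericVector n,
                                double palm, double fop) {
  NumericVector out(b.size());
  for (int i = 0; i < b.size(); ++i)
    out[i] = f_leave((ll)b[i], (ll)n[i], palm, fop);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_perm_in(NumericVector b, NumericVector n,
                                  double pnpp, int lam, double fde) {
  NumericVector out(b.size());
  for (int i = 0; i < b.size(); ++i)
    out[i] = f_perm_in((ll)b[i], (ll)n[i], pnpp, lam, fde);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_division(NumericVector b, double pcd, int lam) {
  NumericVector out(b.size());
  for (int i = 0; i < b.size(); ++i) out[i] = f_division((ll)b[i], pcd, lam);
  return out;
}
// [[Rcpp::export]]
NumericVector cpp_formula_move(IntegerVector m, double pmv) {
  NumericVector out(m.size());
  for (int i = 0; i < m.size(); ++i) out[i] = f_move(m[i], pmv);
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_classify(CharacterVector seqs, std::string tag,
                           std::string rep, std::string nsr) {
  SeqSet cs;
  cs.tag = encode_seq(tag);
  cs.rep = encode_seq(rep);
  cs.nsr = encode_seq(nsr);
  cs.rep_rc = revcomp(cs.rep);
  cs.nsr_rc = revcomp(cs.nsr);
  cs.tag_rep = cs.tag;
  cs.tag_rep.insert(cs.tag_rep.end(), cs.rep.begin(), cs.rep.end());
  IntegerVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = (int)classify_seq(encode_seq(as<std::string>(seqs[i])), cs);
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector seqs) {
  CharacterVector out(seqs.size());
  for (int i = 0; i < seqs.size(); ++i)
    out[i] = decode_seq(revcomp(encode_seq(as<std::string>(seqs[i]))));
  return out;
}
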