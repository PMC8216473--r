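#include <Rcpp.h>
using namespace Rcpp;

// Seed-anchored miRNA::target co-fold under an additive energy model.
//
// Coordinates are 1-based within the two sequences. The miRNA runs 5'->3'
// over positions 1..M; the target window runs 5'->3' over 1..T. Pairing is
// antiparallel: if miRNA position i pairs target position j, any further
// pair (i', j') must have i' > i and j' < j. The seed block
// mir[seed_start .. seed_start+seed_len-1] is forced onto
// win[anchor+seed_len-1 .. anchor] (Watson-Crick only) and extensions on
// both sides are optimised independently by dynamic programming. Unpaired
// nucleotides between consecutive pairs cost bulge_per_nt (gap on one
// strand) or loop_per_nt (gaps on both strands); dangling ends are free.
// Gaps between consecutive pairs are capped at max_gap nt per strand.

static inline double pair_energy(char a, char b, double e_gc, double e_au,
                                 double e_gu) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return e_gc;
  if ((a == 'A' && b == 'U') || (a == 'U' && b == 'A')) return e_au;
  if ((a == 'G' && b == 'U') || (a == 'U' && b == 'G')) return e_gu;
  return NA_REAL;
}

static inline double gap_cost(int a, int b, double bulge, double loop) {
  if (a == 0 && b == 0) return 0.0;
  if (a > 0 && b > 0) return loop * (a + b);
  return bulge * (a + b);
}

struct DpCtx {
  const std::string *mir, *win;
  double e_gc, e_au, e_gu, bulge, loop;
  int max_gap, M, T;
  std::vector<double> memo;
  std::vector<int> choice;  // encoded best next pair, -1 = stop
  int dir;                  // +1: extend i up / j down; -1: mirrored
};

// Best additional energy when the last placed pair is (i, j).
static double extend(DpCtx &c, int i, int j) {
  int idx = (i - 1) * c.T + (j - 1);
  if (!ISNA(c.memo[idx])) return c.memo[idx];
  double best = 0.0;
  int best_choice = -1;
  for (int gi = 0; gi <= c.max_gap; ++gi) {
    int i2 = i + c.dir * (gi + 1);
    if (i2 < 1 || i2 > c.M) break;
    for (int gj = 0; gj <= c.max_gap; ++gj) {
      int j2 = j - c.dir * (gj + 1);
      if (j2 < 1 || j2 > c.T) break;
      double pe = pair_energy((*c.mir)[i2 - 1], (*c.win)[j2 - 1], c.e_gc,
                              c.e_au, c.e_gu);
      if (ISNA(pe)) continue;
      double tot = gap_cost(gi, gj, c.bulge, c.loop) + pe + extend(c, i2, j2);
      if (tot < best - 1e-12) {
        best = tot;
        best_choice = (i2 - 1) * c.T + (j2 - 1);
      }
    }
  }
  c.memo[idx] = best;
  c.choice[idx] = best_choice;
  return best;
}

static void traceback(DpCtx &c, int i, int j, std::vector<int> &mir_pos,
                      std::vector<int> &win_pos) {
  int idx = (i - 1) * c.T + (j - 1);
  while (c.choice[idx] != -1) {
    int nxt = c.choice[idx];
    int i2 = nxt / c.T + 1, j2 = nxt % c.T + 1;
    mir_pos.push_back(i2);
    win_pos.push_back(j2);
    idx = nxt;
  }
}

// [[Rcpp::export]]
List duplex_dp_cpp(std::string mir, std::string win, int anchor,
                   int seed_start, int seed_len, double e_gc, double e_au,
                   double e_gu, double bulge_per_nt, double loop_per_nt,
                   double init_penalty, int max_gap) {
  int M = mir.size(), T = win.size();
  if (anchor < 1 || anchor + seed_len - 1 > T)
    stop("seed anchor outside the target window");
  if (seed_start < 1 || seed_start + seed_len - 1 > M)
    stop("seed window outside the miRNA");

  // Forced seed block: mir[seed_start + t] pairs win[anchor + seed_len-1 - t],
  // Watson-Crick only.
  double seed_e = 0.0;
  std::vector<int> mir_pos, win_pos;
  for (int t = 0; t < seed_len; ++t) {
    char a = mir[seed_start - 1 + t];
    char b = win[anchor - 1 + seed_len - 1 - t];
    double pe = pair_energy(a, b, e_gc, e_au, e_gu);
    bool wc = !ISNA(pe) && !((a == 'G' && b == 'U') || (a == 'U' && b == 'G'));
    if (!wc) return List::create(_["ok"] = false);
    seed_e += pe;
    mir_pos.push_back(seed_start + t);
    win_pos.push_back(anchor + seed_len - 1 - t);
  }

  DpCtx up;  // 3' side of the miRNA: i increases, j decreases
  up.mir = &mir; up.win = &win;
  up.e_gc = e_gc; up.e_au = e_au; up.e_gu = e_gu;
  up.bulge = bulge_per_nt; up.loop = loop_per_nt;
  up.max_gap = max_gap; up.M = M; up.T = T; up.dir = 1;
  up.memo.assign((size_t)M * T, NA_REAL);
  up.choice.assign((size_t)M * T, -1);
  double e3 = extend(up, seed_start + seed_len - 1, anchor);
  traceback(up, seed_start + seed_len - 1, anchor, mir_pos, win_pos);

  DpCtx down = up;  // 5' side: i decreases, j increases
  down.dir = -1;
  down.memo.assign((size_t)M * T, NA_REAL);
  down.choice.assign((size_t)M * T, -1);
  double e5 = extend(down, seed_start, anchor + seed_len - 1);
  traceback(down, seed_start, anchor + seed_len - 1, mir_pos, win_pos);

  double mfe = init_penalty + seed_e + e3 + e5;
  return List::create(_["ok"] = true, _["mfe"] = mfe,
                      _["mir_pos"] = wrap(mir_pos),
                      _["win_pos"] = wrap(win_pos));
}
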