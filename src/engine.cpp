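// Kinetic Monte Carlo kernel for the multilane variable-step exclusion
// process.  Uniformized random-sequential updating: one Monte Carlo step
// (MCS) consists of (N + Ly) elementary draws with replacement over the
// current agents -- the N resident particles plus one entrance slot per
// lane -- so every agent is visited once per MCS on average and the
// dynamics is the discrete skeleton of the continuous-time process.  The
// engine owns its RNG (mt19937_64 seeded from the config) so that runs are
// bit-reproducible independently of R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Rng {
  std::mt19937_64 gen;
  explicit Rng(uint64_t seed) : gen(seed) {}
  // 53-bit uniform in [0,1); avoids implementation-defined distributions
  double u() { return (gen() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return static_cast<int>(gen() % static_cast<uint64_t>(n)); }
};

const int EMPTY = -1;

struct Events {
  std::vector<double> t;
  std::vector<int> id, lane, col, dx, dy, type;
  bool on, truncated;
  int cap;
  Events(bool on_, int cap_) : on(on_), truncated(false), cap(cap_) {}
  void push(double t_, int id_, int lane_, int col_, int dx_, int dy_,
            int type_) {
    if (!on) return;
    if ((int)t.size() >= cap) { truncated = true; return; }
    t.push_back(t_); id.push_back(id_); lane.push_back(lane_);
    col.push_back(col_); dx.push_back(dx_); dy.push_back(dy_);
    type.push_back(type_);
  }
};

} // namespace

// [[Rcpp::export(name = ".sim_core")]]
List sim_core(int Lx, int Ly,
              double alpha, double beta,
              double Patt, double Pdet, double Satt, double Sdet,
              double Px, double Py,
              int warmup, int sample,
              double seed,
              IntegerMatrix init,      // Ly x Lx occupancy (0/1), or 0 x 0
              bool init_primary, int init_s,
              bool entry_stationary,   // entrants drawn from stationary ATP law
              bool periodic_x,
              bool record_events, int max_events,
              int nblocks, bool check)
{
  if (Lx < 1 || Ly < 1) stop("invalid lattice dimensions");
  if (sample < 1) stop("sample window must be at least 1 MCS");
  const int nsite = Lx * Ly;

  Rng rng(static_cast<uint64_t>(seed));

  std::vector<int> occ(nsite, EMPTY);        // particle slot or EMPTY
  // particle attribute arrays (slot index; arrays grow monotonically)
  std::vector<int>  p_lane, p_col, p_id;
  std::vector<double> p_ten;
  std::vector<char> p_prim, p_s, p_alive;
  std::vector<int>  alive;                   // live particle slots
  std::vector<int>  where;                   // slot -> position in `alive`
  int next_id = 1;

  Events ev(record_events, max_events);

  const double p_stat = (Patt + Pdet > 0) ? Patt / (Patt + Pdet) : 0.0;
  const double s_stat = (Satt + Sdet > 0) ? Satt / (Satt + Sdet) : 0.0;

  auto idx = [Lx](int l, int c) { return l * Lx + c; };

  auto spawn = [&](int l, int c, bool prim, int s, double t) {
    int slot = (int)p_lane.size();
    p_lane.push_back(l); p_col.push_back(c);
    p_prim.push_back(prim ? 1 : 0); p_s.push_back((char)s);
    p_id.push_back(next_id); p_ten.push_back(t); p_alive.push_back(1);
    occ[idx(l, c)] = slot;
    where.push_back((int)alive.size());
    alive.push_back(slot);
    ev.push(t, next_id, l + 1, c + 1, 0, 0, 0); // type 0 = enter
    ++next_id;
  };

  auto remove_particle = [&](int slot) {
    p_alive[slot] = 0;
    int pos = where[slot], last = alive.back();
    alive[pos] = last; where[last] = pos;
    alive.pop_back();
  };

  // initial configuration
  if (init.nrow() > 0) {
    if (init.nrow() != Ly || init.ncol() != Lx)
      stop("init occupancy must be a Ly x Lx matrix");
    for (int c = 0; c < Lx; ++c)
      for (int l = 0; l < Ly; ++l)
        if (init(l, c) != 0) spawn(l, c, init_primary, init_s, 0.0);
  }

  // accumulators (sampling window only, except the inject/extract totals)
  std::vector<int> dens(nsite, 0);
  std::vector<double> bond(Lx, 0.0);  // bond c = between columns c,c+1
                                      // (0-based); bond Lx-1 = exit/wrap bond
  long long jump_long[4] = {0, 0, 0, 0};
  long long jump_trans[4] = {0, 0, 0, 0};
  long long up_cross = 0, down_cross = 0;
  long long n_inject = 0, n_extract = 0;
  if (nblocks < 1) nblocks = 1;
  std::vector<double> blk_bulk(nblocks, 0.0), blk_J(nblocks, 0.0),
      blk_trans(nblocks, 0.0);
  std::vector<int> blk_len(nblocks, 0);
  const int mid_lo = Lx / 4;            // middle half of columns, 0-based
  const int mid_hi = (3 * Lx) / 4;      // [mid_lo, mid_hi)
  const int mid_w = mid_hi - mid_lo;

  const int n_entr = periodic_x ? 0 : Ly;   // entrance agents (open ends only)
  const int total = warmup + sample;

  for (int t = 1; t <= total; ++t) {
    const bool sampling = (t > warmup);
    const int blk = sampling
      ? (int)(((long long)(t - warmup - 1)) * nblocks / sample) : 0;

    const int K = n_entr + (int)alive.size();  // draws this MCS
    for (int j = 0; j < K; ++j) {
      const double tfrac = (t - 1) + (double)j / (double)K;
      const int nag = n_entr + (int)alive.size();
      if (nag == 0) break;
      const int a = rng.below(nag);

      if (a < n_entr) {
        // ---- entrance slot: injection trial into lane a ----
        const int l = a;
        if (occ[idx(l, 0)] == EMPTY && rng.u() < alpha) {
          bool prim = false; int s = 0;
          if (entry_stationary) {
            prim = rng.u() < p_stat;
            for (int k = 0; k < 3; ++k) if (rng.u() < s_stat) ++s;
          }
          spawn(l, 0, prim, s, tfrac);
          ++n_inject;
        }
        continue;
      }

      const int pp = alive[a - n_entr];

      // --- internal ATP kinetics: one trial per binding site per draw ---
      if (p_prim[pp]) { if (rng.u() < Pdet) p_prim[pp] = 0; }
      else            { if (rng.u() < Patt) p_prim[pp] = 1; }
      {
        int s = p_s[pp], ns = 0;
        for (int k = 0; k < s; ++k)     if (rng.u() >= Sdet) ++ns; // stays
        for (int k = 0; k < 3 - s; ++k) if (rng.u() < Satt)  ++ns; // attaches
        p_s[pp] = (char)ns;
      }
      if (!p_prim[pp]) continue;          // movement needs the hydrolysis site
      const int n = 4 - p_s[pp];          // intended jump length, 1..4

      const double u = rng.u();
      const int l = p_lane[pp], c = p_col[pp];

      if (u < Px) {
        // ---- forward move along the lane ----
        if (periodic_x) {
          int g = 0;
          while (g < n && occ[idx(l, (c + g + 1) % Lx)] == EMPTY) ++g;
          if (g > 0) {
            int nc = (c + g) % Lx;
            occ[idx(l, c)] = EMPTY; occ[idx(l, nc)] = pp;
            p_col[pp] = nc; p_prim[pp] = 0;      // hydrolysis on a realized hop
            if (sampling) {
              jump_long[g - 1]++;
              for (int b = 0; b < g; ++b) bond[(c + b) % Lx] += 1.0;
              blk_J[blk] += g;
            }
            ev.push(tfrac, p_id[pp], l + 1, nc + 1, g, 0, 1);
          }
        } else {
          const int to_end = Lx - 1 - c;          // free run up to column Lx
          const int limit = std::min(n, to_end);
          int g = 0;
          while (g < limit && occ[idx(l, c + g + 1)] == EMPTY) ++g;
          if (c + n > Lx - 1 && g == to_end) {
            // assigned jump reaches or passes the last column on a clear
            // path: exit trial folded into the move
            if (rng.u() < beta) {
              const int d = to_end + 1;           // crosses the exit bond
              occ[idx(l, c)] = EMPTY;
              remove_particle(pp);
              ++n_extract;
              if (sampling) {
                jump_long[d - 1]++;
                for (int b = c; b <= Lx - 1; ++b) bond[b] += 1.0;
                blk_J[blk] += d;
              }
              ev.push(tfrac, p_id[pp], l + 1, Lx + 1, d, 0, 2); // 2 = exit
            } else if (to_end > 0) {
              // failed exit: placed at the last column
              occ[idx(l, c)] = EMPTY; occ[idx(l, Lx - 1)] = pp;
              p_col[pp] = Lx - 1; p_prim[pp] = 0;
              if (sampling) {
                jump_long[to_end - 1]++;
                for (int b = c; b < Lx - 1; ++b) bond[b] += 1.0;
                blk_J[blk] += to_end;
              }
              ev.push(tfrac, p_id[pp], l + 1, Lx, to_end, 0, 1);
            } // at column Lx already: stays put, ATP retained
          } else if (g > 0) {
            // ordinary slide: land on the last empty site before an obstacle
            const int nc = c + g;
            occ[idx(l, c)] = EMPTY; occ[idx(l, nc)] = pp;
            p_col[pp] = nc; p_prim[pp] = 0;
            if (sampling) {
              jump_long[g - 1]++;
              for (int b = c; b < nc; ++b) bond[b] += 1.0;
              blk_J[blk] += g;
            }
            ev.push(tfrac, p_id[pp], l + 1, nc + 1, g, 0, 1);
          }
        }
      } else if (u < Px + 2 * Py && Ly > 1) {
        // ---- transverse move on the lane ring ----
        const int dir = (u < Px + Py) ? 1 : -1;   // up / down
        int k = 0;
        while (k < n) {
          int tl = (l + dir * (k + 1)) % Ly; if (tl < 0) tl += Ly;
          if (tl != l && occ[idx(tl, c)] != EMPTY) break; // origin is vacated
          ++k;
        }
        if (k > 0) {
          int nl = (l + dir * k) % Ly; if (nl < 0) nl += Ly;
          occ[idx(l, c)] = EMPTY; occ[idx(nl, c)] = pp;
          p_lane[pp] = nl; p_prim[pp] = 0;
          if (sampling) {
            jump_trans[k - 1]++;
            if (dir > 0) up_cross += k; else down_cross += k;
            blk_trans[blk] += dir * k;
          }
          ev.push(tfrac, p_id[pp], nl + 1, c + 1, 0, dir * k, 1);
        }
      }
      // leftover probability mass (Px + 2Py < 1): no move attempted
    }

    if (sampling) {
      blk_len[blk] += 1;
      int nm = 0;
      for (int ai = 0; ai < (int)alive.size(); ++ai) {
        const int pp = alive[ai];
        dens[idx(p_lane[pp], p_col[pp])] += 1;
        if (p_col[pp] >= mid_lo && p_col[pp] < mid_hi) ++nm;
      }
      blk_bulk[blk] += (double)nm / (double)(mid_w * Ly);
    }

    if (check) {
      int nocc = 0;
      for (int i = 0; i < nsite; ++i) {
        if (occ[i] == EMPTY) continue;
        ++nocc;
        const int pp = occ[i];
        if (!p_alive[pp] || idx(p_lane[pp], p_col[pp]) != i)
          stop("occupancy/registry inconsistency at MCS %d", t);
      }
      if (nocc != (int)alive.size())
        stop("exclusion violated: %d occupied cells vs %d particles at MCS %d",
             nocc, (int)alive.size(), t);
      for (size_t i = 0; i < alive.size(); ++i)
        if (where[alive[i]] != (int)i)
          stop("live-list index corrupted at MCS %d", t);
    }

    if ((t & 1023) == 0) Rcpp::checkUserInterrupt();
  }

  // assemble results
  NumericMatrix density(Ly, Lx);
  for (int l = 0; l < Ly; ++l)
    for (int c = 0; c < Lx; ++c)
      density(l, c) = (double)dens[idx(l, c)] / (double)sample;

  NumericVector bond_raw(Lx);
  for (int c = 0; c < Lx; ++c) bond_raw[c] = bond[c];

  NumericVector bb(nblocks), bj(nblocks), bt(nblocks);
  for (int b = 0; b < nblocks; ++b) {
    const double len = blk_len[b] > 0 ? (double)blk_len[b] : 1.0;
    bb[b] = blk_bulk[b] / len;
    bj[b] = blk_J[b] / (len * Lx * Ly);          // spatially averaged current
    bt[b] = blk_trans[b] / (len * Lx * Ly);      // net transverse analogue
  }

  const int nfin = (int)alive.size();
  IntegerVector fin_lane(nfin), fin_col(nfin), fin_id(nfin), fin_s(nfin);
  NumericVector fin_ten(nfin);
  LogicalVector fin_prim(nfin);
  for (int i = 0; i < nfin; ++i) {
    const int pp = alive[i];
    fin_lane[i] = p_lane[pp] + 1; fin_col[i] = p_col[pp] + 1;
    fin_id[i] = p_id[pp]; fin_s[i] = p_s[pp];
    fin_prim[i] = p_prim[pp] != 0; fin_ten[i] = p_ten[pp];
  }

  List events = R_NilValue;
  if (record_events) {
    events = List::create(
      _["t"] = wrap(ev.t), _["id"] = wrap(ev.id), _["lane"] = wrap(ev.lane),
      _["col"] = wrap(ev.col), _["dx"] = wrap(ev.dx), _["dy"] = wrap(ev.dy),
      _["type"] = wrap(ev.type), _["truncated"] = ev.truncated);
  }

  return List::create(
    _["density"] = density,
    _["bond_raw"] = bond_raw,
    _["jump_long"] = NumericVector::create(jump_long[0], jump_long[1],
                                           jump_long[2], jump_long[3]),
    _["jump_trans"] = NumericVector::create(jump_trans[0], jump_trans[1],
                                            jump_trans[2], jump_trans[3]),
    _["up_cross"] = (double)up_cross,
    _["down_cross"] = (double)down_cross,
    _["block_bulk"] = bb,
    _["block_J"] = bj,
    _["block_trans"] = bt,
    _["n_injected"] = (double)n_inject,
    _["n_extracted"] = (double)n_extract,
    _["final"] = List::create(_["id"] = fin_id, _["lane"] = fin_lane,
                              _["col"] = fin_col, _["primary"] = fin_prim,
                              _["s"] = fin_s, _["t_en"] = fin_ten),
    _["events"] = events);
}
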