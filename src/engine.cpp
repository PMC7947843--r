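// Pruning-likelihood engine for gene-tree estimation.
//
// Felsenstein pruning over compressed site patterns with discrete-gamma rate
// mixtures, per-edge Brent branch-length optimization using directional
// partials (one post-order "down" pass per optimization cycle, then a
// pre-order sweep that maintains the "above" partial), partitioned
// (edge-linked, proportional-rate) multi-block likelihoods, and a
// first-improvement NNI hill climb that can be restricted by bipartition
// constraints.  Trees use ape's node numbering: tips 1..ntip, root ntip+1.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static const double MINBL = 1e-8;
static const double MAXBL = 10.0;
static const double SCALE_THRESH = 1e-140;
static const double SCALE_FACTOR = 1e140;
static const double LOG_SCALE = std::log(SCALE_FACTOR);

struct Block {
  int npat, ncat;
  std::vector<double> w;            // pattern weights
  std::vector<int> tipstate;        // ntip x npat ambiguity masks (bit0=A..bit3=T)
  double U[16], Uinv[16], lam[4], pi[4];
  std::vector<double> rates;        // ncat relative rates (mean 1)
  double rmult;                     // block rate multiplier on shared edges
  // workspace, indexed by node
  std::vector<std::vector<double> > down, A;
  std::vector<std::vector<double> > sdown, sA;
};

struct Engine {
  int ntip, nnode, root;
  std::vector<int> parent;                 // -1 for root
  std::vector<double> plen;                // branch above node
  std::vector<std::vector<int> > kids;
  std::vector<Block> blocks;

  // ---- tree wiring -------------------------------------------------------
  void build_tree(const IntegerMatrix &edge, const NumericVector &elen, int ntip_) {
    ntip = ntip_;
    int mx = ntip;
    for (int i = 0; i < edge.nrow(); ++i) {
      mx = std::max(mx, std::max(edge(i, 0), edge(i, 1)));
    }
    nnode = mx;
    parent.assign(nnode, -1);
    plen.assign(nnode, 0.0);
    kids.assign(nnode, std::vector<int>());
    for (int i = 0; i < edge.nrow(); ++i) {
      int p = edge(i, 0) - 1, c = edge(i, 1) - 1;
      parent[c] = p;
      plen[c] = elen[i];
      kids[p].push_back(c);
    }
    root = -1;
    for (int v = ntip; v < nnode; ++v) if (parent[v] < 0) { root = v; break; }
    if (root < 0) stop("engine: no root found");
  }

  void postorder(std::vector<int> &ord) const {
    ord.clear(); ord.reserve(nnode);
    std::vector<int> stack; stack.push_back(root);
    std::vector<int> out;
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      out.push_back(v);
      for (size_t i = 0; i < kids[v].size(); ++i) stack.push_back(kids[v][i]);
    }
    for (int i = (int)out.size() - 1; i >= 0; --i) ord.push_back(out[i]);
  }

  // ---- transition matrices ----------------------------------------------
  // P[r][i*4+j] for each rate category at effective length t*rate[r]*rmult
  void pmat(const Block &b, double t, std::vector<double> &P) const {
    P.assign(b.ncat * 16, 0.0);
    for (int r = 0; r < b.ncat; ++r) {
      double tr = t * b.rates[r] * b.rmult;
      double ex[4];
      for (int k = 0; k < 4; ++k) ex[k] = std::exp(b.lam[k] * tr);
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j) {
          double s = 0.0;
          for (int k = 0; k < 4; ++k) s += b.U[i * 4 + k] * ex[k] * b.Uinv[k * 4 + j];
          P[r * 16 + i * 4 + j] = s > 0 ? s : 0.0;
        }
    }
  }

  void alloc_work() {
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      b.down.assign(nnode, std::vector<double>());
      b.sdown.assign(nnode, std::vector<double>());
      b.A.assign(nnode, std::vector<double>());
      b.sA.assign(nnode, std::vector<double>());
    }
  }

  // ---- down (post-order) partials ---------------------------------------
  void down_node(Block &b, int v) {
    int sz = b.npat * b.ncat * 4;
    b.down[v].assign(sz, 1.0);
    b.sdown[v].assign(b.npat, 0.0);
    if (v < ntip) {
      for (int p = 0; p < b.npat; ++p) {
        int mask = b.tipstate[(size_t)v * b.npat + p];
        if (mask <= 0 || mask > 15) mask = 15;
        for (int r = 0; r < b.ncat; ++r)
          for (int j = 0; j < 4; ++j)
            b.down[v][(size_t)p * b.ncat * 4 + r * 4 + j] = (mask >> j) & 1 ? 1.0 : 0.0;
      }
      return;
    }
    std::vector<double> P;
    for (size_t ci = 0; ci < kids[v].size(); ++ci) {
      int c = kids[v][ci];
      pmat(b, plen[c], P);
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        for (int r = 0; r < b.ncat; ++r) {
          const double *dn = &b.down[c][off + r * 4];
          const double *Pr = &P[r * 16];
          for (int i = 0; i < 4; ++i) {
            double m = Pr[i * 4 + 0] * dn[0] + Pr[i * 4 + 1] * dn[1] +
                       Pr[i * 4 + 2] * dn[2] + Pr[i * 4 + 3] * dn[3];
            b.down[v][off + r * 4 + i] *= m;
          }
        }
        b.sdown[v][p] += b.sdown[c][p];
      }
    }
    // rescale per pattern
    for (int p = 0; p < b.npat; ++p) {
      size_t off = (size_t)p * b.ncat * 4;
      double mx = 0.0;
      for (int k = 0; k < b.ncat * 4; ++k) mx = std::max(mx, b.down[v][off + k]);
      if (mx > 0 && mx < SCALE_THRESH) {
        for (int k = 0; k < b.ncat * 4; ++k) b.down[v][off + k] *= SCALE_FACTOR;
        b.sdown[v][p] -= LOG_SCALE;
      }
    }
  }

  void down_pass() {
    std::vector<int> ord;
    postorder(ord);
    for (size_t bi = 0; bi < blocks.size(); ++bi)
      for (size_t i = 0; i < ord.size(); ++i) down_node(blocks[bi], ord[i]);
  }

  // total log-likelihood at the root given fresh down partials
  double root_loglik(std::vector<double> *site = NULL) {
    double tot = 0.0;
    if (site) site->clear();
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        double s = 0.0;
        for (int r = 0; r < b.ncat; ++r)
          for (int i = 0; i < 4; ++i)
            s += b.pi[i] * b.down[root][off + r * 4 + i];
        s /= b.ncat;
        double lp = std::log(s) + b.sdown[root][p];
        tot += b.w[p] * lp;
        if (site) site->push_back(lp);
      }
    }
    return tot;
  }

  double loglik_full(std::vector<double> *site = NULL) {
    down_pass();
    return root_loglik(site);
  }

  // ---- edge objective given B (above) and down(child) -------------------
  // B is stored in blk.A[child] slot? No: passed explicitly.
  double edge_loglik(double t, std::vector<std::vector<double> > &Bv,
                     std::vector<std::vector<double> > &sBv, int child) {
    double tot = 0.0;
    std::vector<double> P;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      pmat(b, t, P);
      const std::vector<double> &B = Bv[bi];
      const std::vector<double> &sB = sBv[bi];
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        double s = 0.0;
        for (int r = 0; r < b.ncat; ++r) {
          const double *dn = &b.down[child][off + r * 4];
          const double *Bk = &B[off + r * 4];
          const double *Pr = &P[r * 16];
          for (int k = 0; k < 4; ++k) {
            double m = Pr[k * 4 + 0] * dn[0] + Pr[k * 4 + 1] * dn[1] +
                       Pr[k * 4 + 2] * dn[2] + Pr[k * 4 + 3] * dn[3];
            s += Bk[k] * m;
          }
        }
        s /= b.ncat;
        if (s <= 0) s = 1e-300;
        tot += b.w[p] * (std::log(s) + sB[p] + b.sdown[child][p]);
      }
    }
    return tot;
  }

  // Brent minimizer (local, on negative edge log-likelihood)
  template <typename F>
  double brent(F f, double ax, double bx, double cx, double tol, double &fmin) {
    const int ITMAX = 60;
    const double CGOLD = 0.3819660, ZEPS = 1e-6;
    double a = std::min(ax, cx), b2 = std::max(ax, cx);
    double x = bx, w2 = bx, v = bx;
    double fx = f(x), fw = fx, fv = fx;
    double d = 0.0, e = 0.0;
    for (int it = 0; it < ITMAX; ++it) {
      double xm = 0.5 * (a + b2);
      double tol1 = tol * std::fabs(x) + ZEPS, tol2 = 2 * tol1;
      if (std::fabs(x - xm) <= (tol2 - 0.5 * (b2 - a))) break;
      double dd = 0.0; bool para = false;
      if (std::fabs(e) > tol1) {
        double r = (x - w2) * (fx - fv);
        double q = (x - v) * (fx - fw);
        double pp = (x - v) * q - (x - w2) * r;
        q = 2.0 * (q - r);
        if (q > 0.0) pp = -pp;
        q = std::fabs(q);
        double etemp = e; e = d;
        if (!(std::fabs(pp) >= std::fabs(0.5 * q * etemp) || pp <= q * (a - x) ||
              pp >= q * (b2 - x))) {
          d = pp / q; double u = x + d; para = true;
          if (u - a < tol2 || b2 - u < tol2) d = (xm - x >= 0 ? tol1 : -tol1);
        }
      }
      if (!para) { e = (x >= xm ? a - x : b2 - x); d = CGOLD * e; }
      dd = (std::fabs(d) >= tol1 ? d : (d >= 0 ? tol1 : -tol1));
      double u = x + dd;
      double fu = f(u);
      if (fu <= fx) {
        if (u >= x) a = x; else b2 = x;
        v = w2; w2 = x; x = u; fv = fw; fw = fx; fx = fu;
      } else {
        if (u < x) a = u; else b2 = u;
        if (fu <= fw || w2 == x) { v = w2; w2 = u; fv = fw; fw = fu; }
        else if (fu <= fv || v == x || v == w2) { v = u; fv = fu; }
      }
    }
    fmin = fx;
    return x;
  }

  // compute B = A[u] (*) prod of sibling messages, for child c of u
  void make_B(int u, int c, std::vector<std::vector<double> > &Bv,
              std::vector<std::vector<double> > &sBv) {
    Bv.assign(blocks.size(), std::vector<double>());
    sBv.assign(blocks.size(), std::vector<double>());
    std::vector<double> P;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      int sz = b.npat * b.ncat * 4;
      Bv[bi].assign(sz, 0.0);
      sBv[bi].assign(b.npat, 0.0);
      for (int k = 0; k < sz; ++k) Bv[bi][k] = b.A[u][k];
      for (int p = 0; p < b.npat; ++p) sBv[bi][p] = b.sA[u][p];
      for (size_t si = 0; si < kids[u].size(); ++si) {
        int s = kids[u][si];
        if (s == c) continue;
        pmat(b, plen[s], P);
        for (int p = 0; p < b.npat; ++p) {
          size_t off = (size_t)p * b.ncat * 4;
          for (int r = 0; r < b.ncat; ++r) {
            const double *dn = &b.down[s][off + r * 4];
            const double *Pr = &P[r * 16];
            for (int k = 0; k < 4; ++k) {
              double m = Pr[k * 4 + 0] * dn[0] + Pr[k * 4 + 1] * dn[1] +
                         Pr[k * 4 + 2] * dn[2] + Pr[k * 4 + 3] * dn[3];
              Bv[bi][off + r * 4 + k] *= m;
            }
          }
          sBv[bi][p] += b.sdown[s][p];
        }
      }
      // rescale
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        double mx = 0.0;
        for (int k = 0; k < b.ncat * 4; ++k) mx = std::max(mx, Bv[bi][off + k]);
        if (mx > 0 && mx < SCALE_THRESH) {
          for (int k = 0; k < b.ncat * 4; ++k) Bv[bi][off + k] *= SCALE_FACTOR;
          sBv[bi][p] -= LOG_SCALE;
        }
      }
    }
  }

  // set A[c] from B and branch length of c
  void set_A(int c, std::vector<std::vector<double> > &Bv,
             std::vector<std::vector<double> > &sBv) {
    std::vector<double> P;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      int sz = b.npat * b.ncat * 4;
      b.A[c].assign(sz, 0.0);
      b.sA[c].assign(b.npat, 0.0);
      pmat(b, plen[c], P);
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        for (int r = 0; r < b.ncat; ++r) {
          const double *Pr = &P[r * 16];
          const double *Bk = &Bv[bi][off + r * 4];
          for (int i = 0; i < 4; ++i) {
            double s = 0.0;
            for (int k = 0; k < 4; ++k) s += Bk[k] * Pr[k * 4 + i];
            b.A[c][off + r * 4 + i] = s;
          }
        }
        b.sA[c][p] = sBv[bi][p];
        double mx = 0.0;
        for (int k = 0; k < b.ncat * 4; ++k) mx = std::max(mx, b.A[c][off + k]);
        if (mx > 0 && mx < SCALE_THRESH) {
          for (int k = 0; k < b.ncat * 4; ++k) b.A[c][off + k] *= SCALE_FACTOR;
          b.sA[c][p] -= LOG_SCALE;
        }
      }
    }
  }

  void init_A_root() {
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      int sz = b.npat * b.ncat * 4;
      b.A[root].assign(sz, 0.0);
      b.sA[root].assign(b.npat, 0.0);
      for (int p = 0; p < b.npat; ++p)
        for (int r = 0; r < b.ncat; ++r)
          for (int i = 0; i < 4; ++i)
            b.A[root][(size_t)p * b.ncat * 4 + r * 4 + i] = b.pi[i];
    }
  }

  // one optimization pass over all edges (pre-order); returns final lnL.
  // optimize=false just refreshes partials and returns lnL.
  double opt_pass(bool optimize) {
    down_pass();
    init_A_root();
    double lnl = root_loglik();
    // iterative pre-order with explicit stack
    std::vector<int> stack;
    stack.push_back(root);
    std::vector<std::vector<double> > Bv, sBv;
    while (!stack.empty()) {
      int u = stack.back(); stack.pop_back();
      for (size_t ci = 0; ci < kids[u].size(); ++ci) {
        int c = kids[u][ci];
        make_B(u, c, Bv, sBv);
        if (optimize) {
          double t0 = plen[c];
          double f0 = edge_loglik(t0, Bv, sBv, c);
          double fmin;
          std::vector<std::vector<double> > *Bp = &Bv, *sBp = &sBv;
          Engine *self = this;
          double tbest = brent([self, Bp, sBp, c](double t) {
            return -self->edge_loglik(t, *Bp, *sBp, c);
          }, MINBL, std::max(std::min(t0, MAXBL), MINBL), MAXBL, 2e-4, fmin);
          if (-fmin > f0 + 1e-12) { plen[c] = tbest; lnl = lnl - f0 + (-fmin); }
        }
        set_A(c, Bv, sBv);
        if (c >= ntip) stack.push_back(c);
      }
    }
    return lnl;
  }

  double optimize_edges(int max_passes, double tol) {
    double prev = loglik_full();
    for (int it = 0; it < max_passes; ++it) {
      double cur = opt_pass(true);
      cur = loglik_full();  // consistent final value
      if (cur - prev < tol) return cur;
      prev = cur;
    }
    return prev;
  }

  // optimize only the edge above node v (fresh full passes; used in NNI scoring)
  double optimize_single_edge(int v) {
    down_pass();
    init_A_root();
    // build A chain along path root -> parent(v)
    std::vector<int> path;
    for (int x = parent[v]; x >= 0; x = parent[x]) path.push_back(x);
    std::vector<std::vector<double> > Bv, sBv;
    for (int i = (int)path.size() - 1; i > 0; --i) {
      int u = path[i], c = path[i - 1];
      make_B(u, c, Bv, sBv);
      set_A(c, Bv, sBv);
    }
    int u = parent[v];
    make_B(u, v, Bv, sBv);
    double t0 = plen[v];
    double f0 = edge_loglik(t0, Bv, sBv, v);
    double fmin;
    Engine *self = this;
    std::vector<std::vector<double> > *Bp = &Bv, *sBp = &sBv;
    double tbest = brent([self, Bp, sBp, v](double t) {
      return -self->edge_loglik(t, *Bp, *sBp, v);
    }, MINBL, std::max(std::min(t0, MAXBL), MINBL), MAXBL, 2e-4, fmin);
    if (-fmin > f0) { plen[v] = tbest; return -fmin; }
    return f0;
  }

  // ---- block rate multipliers -------------------------------------------
  double block_loglik(size_t bi) {
    Block &b = blocks[bi];
    std::vector<int> ord;
    postorder(ord);
    for (size_t i = 0; i < ord.size(); ++i) down_node(b, ord[i]);
    double tot = 0.0;
    for (int p = 0; p < b.npat; ++p) {
      size_t off = (size_t)p * b.ncat * 4;
      double s = 0.0;
      for (int r = 0; r < b.ncat; ++r)
        for (int i = 0; i < 4; ++i) s += b.pi[i] * b.down[root][off + r * 4 + i];
      s /= b.ncat;
      tot += b.w[p] * (std::log(s > 0 ? s : 1e-300) + b.sdown[root][p]);
    }
    return tot;
  }

  void optimize_rmult() {
    if (blocks.size() < 2) return;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      double r0 = b.rmult;
      double f0 = block_loglik(bi);
      double fmin;
      Engine *self = this;
      double rbest = brent([self, bi, &b](double r) {
        b.rmult = r;
        return -self->block_loglik(bi);
      }, 1e-4, std::min(std::max(r0, 1e-3), 50.0), 50.0, 1e-7, fmin);
      if (-fmin > f0) b.rmult = rbest; else b.rmult = r0;
    }
    // normalize: site-weighted mean multiplier = 1, fold scale into edges
    double wtot = 0.0, rmean = 0.0;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      double wb = 0.0;
      for (int p = 0; p < blocks[bi].npat; ++p) wb += blocks[bi].w[p];
      wtot += wb; rmean += wb * blocks[bi].rmult;
    }
    rmean /= wtot;
    if (rmean > 0) {
      for (size_t bi = 0; bi < blocks.size(); ++bi) blocks[bi].rmult /= rmean;
      for (int v = 0; v < nnode; ++v) if (v != root) plen[v] = std::min(plen[v] * rmean, MAXBL);
    }
  }

  // ---- splits / constraints ---------------------------------------------
  void below_masks(std::vector<uint64_t> &bm) const {
    bm.assign(nnode, 0);
    std::vector<int> ord;
    postorder(ord);
    for (size_t i = 0; i < ord.size(); ++i) {
      int v = ord[i];
      if (v < ntip) bm[v] = (uint64_t)1 << v;
      else {
        uint64_t m = 0;
        for (size_t c = 0; c < kids[v].size(); ++c) m |= bm[kids[v][c]];
        bm[v] = m;
      }
    }
  }

  bool satisfies(const std::vector<uint64_t> &req) const {
    if (req.empty()) return true;
    std::vector<uint64_t> bm;
    below_masks(bm);
    uint64_t full = (ntip == 64) ? ~(uint64_t)0 : (((uint64_t)1 << ntip) - 1);
    for (size_t i = 0; i < req.size(); ++i) {
      bool ok = false;
      for (int v = 0; v < nnode; ++v) {
        if (v == root) continue;
        if (bm[v] == req[i] || bm[v] == (full ^ req[i])) { ok = true; break; }
      }
      if (!ok) return false;
    }
    return true;
  }

  // ---- NNI ----------------------------------------------------------------
  // swap child a (of u) with child c (of v), where v is a child of u
  void swap_sub(int u, int a, int v, int c) {
    for (size_t i = 0; i < kids[u].size(); ++i) if (kids[u][i] == a) kids[u][i] = c;
    for (size_t i = 0; i < kids[v].size(); ++i) if (kids[v][i] == c) kids[v][i] = a;
    parent[a] = v; parent[c] = u;
  }

  // message vector M = P(plen[x]) down[x] for node x, one block
  void msg(Block &b, int x, std::vector<double> &M) {
    std::vector<double> P;
    pmat(b, plen[x], P);
    M.assign((size_t)b.npat * b.ncat * 4, 0.0);
    for (int p = 0; p < b.npat; ++p) {
      size_t off = (size_t)p * b.ncat * 4;
      for (int r = 0; r < b.ncat; ++r) {
        const double *dn = &b.down[x][off + r * 4];
        const double *Pr = &P[r * 16];
        for (int i = 0; i < 4; ++i)
          M[off + r * 4 + i] = Pr[i * 4 + 0] * dn[0] + Pr[i * 4 + 1] * dn[1] +
                               Pr[i * 4 + 2] * dn[2] + Pr[i * 4 + 3] * dn[3];
      }
    }
  }

  // lnL across the central edge: Us (above side) x P(t) x Ds (below side),
  // with per-block per-pattern scaler sc
  double local_edge_loglik(double t, const std::vector<std::vector<double> > &Us,
                           const std::vector<std::vector<double> > &Ds,
                           const std::vector<std::vector<double> > &sc) {
    double tot = 0.0;
    std::vector<double> P;
    for (size_t bi = 0; bi < blocks.size(); ++bi) {
      Block &b = blocks[bi];
      pmat(b, t, P);
      for (int p = 0; p < b.npat; ++p) {
        size_t off = (size_t)p * b.ncat * 4;
        double s = 0.0;
        for (int r = 0; r < b.ncat; ++r) {
          const double *dn = &Ds[bi][off + r * 4];
          const double *Uk = &Us[bi][off + r * 4];
          const double *Pr = &P[r * 16];
          for (int k = 0; k < 4; ++k) {
            double m = Pr[k * 4 + 0] * dn[0] + Pr[k * 4 + 1] * dn[1] +
                       Pr[k * 4 + 2] * dn[2] + Pr[k * 4 + 3] * dn[3];
            s += Uk[k] * m;
          }
        }
        s /= b.ncat;
        if (s <= 0) s = 1e-300;
        tot += b.w[p] * (std::log(s) + sc[bi][p]);
      }
    }
    return tot;
  }

  // Brent-maximized local lnL for a candidate arrangement of the edge above v
  double local_opt(double t0, const std::vector<std::vector<double> > &Us,
                   const std::vector<std::vector<double> > &Ds,
                   const std::vector<std::vector<double> > &sc) {
    double fmin;
    Engine *self = this;
    brent([self, &Us, &Ds, &sc](double t) {
      return -self->local_edge_loglik(t, Us, Ds, sc);
    }, MINBL, std::max(std::min(t0, MAXBL), MINBL), MAXBL, 2e-4, fmin);
    return -fmin;
  }

  // elementwise product of message/partial vectors, accumulating scalers
  static void had(std::vector<double> &acc, const std::vector<double> &x) {
    for (size_t i = 0; i < acc.size(); ++i) acc[i] *= x[i];
  }

  // constraint check when only below[v] changes to nb
  bool satisfies_with(const std::vector<uint64_t> &req,
                      const std::vector<uint64_t> &bm, int v, uint64_t nb) const {
    if (req.empty()) return true;
    uint64_t full = (ntip == 64) ? ~(uint64_t)0 : (((uint64_t)1 << ntip) - 1);
    for (size_t i = 0; i < req.size(); ++i) {
      bool ok = false;
      for (int w = 0; w < nnode && !ok; ++w) {
        if (w == root) continue;
        uint64_t m = (w == v) ? nb : bm[w];
        if (m == req[i] || m == (full ^ req[i])) ok = true;
      }
      if (!ok) return false;
    }
    return true;
  }

  // NNI hill climb with local candidate scoring; returns lnL.
  double nni_search(const std::vector<uint64_t> &req, int max_sweeps, double min_impr,
                    int opt_passes = 2) {
    double best = optimize_edges(opt_passes, 1e-6);
    size_t nb = blocks.size();
    std::vector<std::vector<double> > Ma(nb), Mb(nb), Ms(nb), Us(nb), Ds(nb), sc(nb);
    for (int sweep = 0; sweep < max_sweeps; ++sweep) {
      bool improved = false;
      opt_pass(false);  // refresh down[] and A[] at current lengths
      std::vector<uint64_t> bmask;
      below_masks(bmask);
      bool stale = false;
      for (int v = ntip; v < nnode; ++v) {
        if (v == root || parent[v] < 0 || kids[v].size() < 2) continue;
        int u = parent[v];
        if (stale) {  // partials invalidated by an accepted move
          opt_pass(false);
          below_masks(bmask);
          stale = false;
        }
        int a = kids[v][0], b2 = kids[v][1];
        std::vector<int> others;
        for (size_t i = 0; i < kids[u].size(); ++i)
          if (kids[u][i] != v) others.push_back(kids[u][i]);
        if (others.empty()) continue;
        for (size_t bi = 0; bi < nb; ++bi) {
          msg(blocks[bi], a, Ma[bi]);
          msg(blocks[bi], b2, Mb[bi]);
        }
        // baseline: optimized current arrangement
        for (size_t bi = 0; bi < nb; ++bi) {
          Block &bk = blocks[bi];
          Us[bi] = bk.A[u];
          sc[bi].assign(bk.npat, 0.0);
          for (int p = 0; p < bk.npat; ++p) sc[bi][p] = bk.sA[u][p];
          Ds[bi] = Ma[bi]; had(Ds[bi], Mb[bi]);
          for (int p = 0; p < bk.npat; ++p)
            sc[bi][p] += bk.sdown[a][p] + bk.sdown[b2][p];
        }
        std::vector<std::vector<double> > Uso = Us;  // A[u] only (with sA scaler)
        // multiply in all "other" children messages for the baseline
        for (size_t oi = 0; oi < others.size(); ++oi) {
          for (size_t bi = 0; bi < nb; ++bi) {
            msg(blocks[bi], others[oi], Ms[bi]);
            had(Us[bi], Ms[bi]);
            for (int p = 0; p < blocks[bi].npat; ++p)
              sc[bi][p] += blocks[bi].sdown[others[oi]][p];
          }
        }
        // every move involves the same subtree set, so the scaler is shared
        std::vector<std::vector<double> > scAll = sc;
        double f0 = local_opt(plen[v], Us, Ds, sc);
        // candidate moves: swap child x of v with sibling s
        for (size_t oi = 0; oi < others.size() && !stale; ++oi) {
          int s = others[oi];
          std::vector<std::vector<double> > Msv(nb);
          for (size_t bi = 0; bi < nb; ++bi) msg(blocks[bi], s, Msv[bi]);
          int cands[2] = {a, b2};
          for (int ci = 0; ci < 2 && !stale; ++ci) {
            int x = cands[ci], keep = (x == a ? b2 : a);
            uint64_t nbv = bmask[keep] | bmask[s];
            if (!satisfies_with(req, bmask, v, nbv)) continue;
            // below side: M_s * M_keep ; above side: A[u] * M_x * other others
            for (size_t bi = 0; bi < nb; ++bi) {
              Block &bk = blocks[bi];
              Ds[bi] = Msv[bi]; had(Ds[bi], (x == a ? Mb : Ma)[bi]);
              Us[bi] = Uso[bi]; had(Us[bi], (x == a ? Ma : Mb)[bi]);
              sc[bi] = scAll[bi];
              for (size_t oj = 0; oj < others.size(); ++oj) {
                if (oj == oi) continue;
                msg(bk, others[oj], Ms[bi]);
                had(Us[bi], Ms[bi]);
              }
            }
            double fc = local_opt(plen[v], Us, Ds, sc);
            if (fc > f0 + min_impr && fc > best) {
              swap_sub(u, s, v, x);
              double cand = optimize_edges(1, 1e-6);
              if (cand > best + min_impr / 10) {
                best = cand;
                improved = true;
                stale = true;
              } else {
                swap_sub(u, x, v, s);  // revert
                stale = true;          // partials touched by optimize_edges
              }
            }
          }
        }
      }
      if (!improved) break;
    }
    return optimize_edges(opt_passes, 1e-6);
  }

  // ---- export ------------------------------------------------------------
  void export_tree(IntegerMatrix &edge, NumericVector &elen) const {
    std::vector<std::pair<int, int> > rows;
    std::vector<int> st2; st2.push_back(root);
    while (!st2.empty()) {
      int v = st2.back(); st2.pop_back();
      for (int i = (int)kids[v].size() - 1; i >= 0; --i) st2.push_back(kids[v][i]);
      if (v != root) rows.push_back(std::make_pair(parent[v], v));
    }
    edge = IntegerMatrix((int)rows.size(), 2);
    elen = NumericVector((int)rows.size());
    for (size_t i = 0; i < rows.size(); ++i) {
      edge(i, 0) = rows[i].first + 1;
      edge(i, 1) = rows[i].second + 1;
      elen[i] = plen[rows[i].second];
    }
  }
};

static void load_blocks(Engine &E, List blocks) {
  E.blocks.clear();
  for (int bi = 0; bi < blocks.size(); ++bi) {
    List bl = blocks[bi];
    Block b;
    IntegerMatrix ts = bl["tipstate"];  // ntip x npat
    NumericVector w = bl["weights"];
    NumericMatrix U = bl["U"], Uinv = bl["Uinv"];
    NumericVector lam = bl["lambda"], pi = bl["pi"], rates = bl["rates"];
    b.npat = ts.ncol();
    b.ncat = rates.size();
    b.w.assign(w.begin(), w.end());
    b.rates.assign(rates.begin(), rates.end());
    b.rmult = bl.containsElementNamed("rmult") ? as<double>(bl["rmult"]) : 1.0;
    b.tipstate.resize((size_t)ts.nrow() * ts.ncol());
    for (int i = 0; i < ts.nrow(); ++i)
      for (int j = 0; j < ts.ncol(); ++j)
        b.tipstate[(size_t)i * ts.ncol() + j] = ts(i, j);
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) {
        b.U[i * 4 + j] = U(i, j);
        b.Uinv[i * 4 + j] = Uinv(i, j);
      }
    for (int i = 0; i < 4; ++i) { b.lam[i] = lam[i]; b.pi[i] = pi[i]; }
    E.blocks.push_back(b);
  }
}

static std::vector<uint64_t> load_constraints(Nullable<NumericMatrix> cons) {
  std::vector<uint64_t> req;
  if (cons.isNotNull()) {
    NumericMatrix cm(cons);
    for (int i = 0; i < cm.nrow(); ++i) {
      uint64_t m = 0;
      for (int j = 0; j < cm.ncol(); ++j) if (cm(i, j) > 0.5) m |= (uint64_t)1 << j;
      req.push_back(m);
    }
  }
  return req;
}

// [[Rcpp::export(name = ".eng_loglik")]]
List eng_loglik(IntegerMatrix edge, NumericVector edge_len, int ntip, List blocks,
                bool per_site = false) {
  Engine E;
  E.build_tree(edge, edge_len, ntip);
  load_blocks(E, blocks);
  E.alloc_work();
  std::vector<double> site;
  double lnl = E.loglik_full(per_site ? &site : NULL);
  List out = List::create(_["loglik"] = lnl);
  if (per_site) out["pattern_loglik"] = NumericVector(site.begin(), site.end());
  return out;
}

// [[Rcpp::export(name = ".eng_optim_edges")]]
List eng_optim_edges(IntegerMatrix edge, NumericVector edge_len, int ntip,
                     List blocks, int max_passes = 20, double tol = 1e-6,
                     bool opt_rmult = false) {
  Engine E;
  E.build_tree(edge, edge_len, ntip);
  load_blocks(E, blocks);
  E.alloc_work();
  double lnl = E.optimize_edges(max_passes, tol);
  if (opt_rmult && E.blocks.size() > 1) {
    for (int round = 0; round < 2; ++round) {
      E.optimize_rmult();
      lnl = E.optimize_edges(5, tol);
    }
  }
  IntegerMatrix oedge; NumericVector oelen;
  E.export_tree(oedge, oelen);
  NumericVector rm(E.blocks.size());
  for (size_t i = 0; i < E.blocks.size(); ++i) rm[i] = E.blocks[i].rmult;
  return List::create(_["edge"] = oedge, _["edge_len"] = oelen,
                      _["loglik"] = lnl, _["rmult"] = rm);
}

// [[Rcpp::export(name = ".eng_search")]]
List eng_search(IntegerMatrix edge, NumericVector edge_len, int ntip, List blocks,
                Nullable<NumericMatrix> constraints = R_NilValue,
                int max_sweeps = 10, double min_impr = 1e-4,
                bool opt_rmult = false, int opt_passes = 2) {
  Engine E;
  E.build_tree(edge, edge_len, ntip);
  load_blocks(E, blocks);
  E.alloc_work();
  std::vector<uint64_t> req = load_constraints(constraints);
  if (!req.empty() && !E.satisfies(req))
    stop("starting tree does not satisfy the constraint");
  double lnl = E.nni_search(req, max_sweeps, min_impr, opt_passes);
  if (opt_rmult && E.blocks.size() > 1) {
    E.optimize_rmult();
    lnl = E.optimize_edges(5, 1e-6);
  }
  IntegerMatrix oedge; NumericVector oelen;
  E.export_tree(oedge, oelen);
  NumericVector rm(E.blocks.size());
  for (size_t i = 0; i < E.blocks.size(); ++i) rm[i] = E.blocks[i].rmult;
  return List::create(_["edge"] = oedge, _["edge_len"] = oelen,
                      _["loglik"] = lnl, _["rmult"] = rm);
}
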