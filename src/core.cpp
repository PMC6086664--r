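#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Connected-component labeling, 8-connected (2D) / 26-connected (3D).
// Scans in R's linear (column-major) order; labels are assigned in order of
// first encounter, so label 1 contains the first foreground pixel in linear
// order.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cq_label")]]
IntegerVector cq_label(LogicalVector mask, IntegerVector dims) {
  const int nd = dims.size();
  const int nr = dims[0], nc = dims[1], np = (nd == 3) ? dims[2] : 1;
  const R_xlen_t n = mask.size();
  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!mask[i] || lab[i]) continue;
    ++next;
    stack.push_back(i);
    lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int p = (int)(cur / ((R_xlen_t)nr * nc));
      int rem = (int)(cur % ((R_xlen_t)nr * nc));
      int c = rem / nr, r = rem % nr;
      for (int dp = -1; dp <= 1; ++dp) {
        int pp = p + dp;
        if (pp < 0 || pp >= np) continue;
        for (int dc = -1; dc <= 1; ++dc) {
          int cc = c + dc;
          if (cc < 0 || cc >= nc) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            if (!dr && !dc && !dp) continue;
            int rr = r + dr;
            if (rr < 0 || rr >= nr) continue;
            R_xlen_t j = (R_xlen_t)pp * nr * nc + (R_xlen_t)cc * nr + rr;
            if (mask[j] && !lab[j]) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
        }
      }
    }
  }
  lab.attr("nlabels") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Livewire: Dijkstra on the 8-connected pixel graph with node costs.
// A step between pixels p and q costs the mean of their node costs times
// the geometric step length (1 axial, sqrt(2) diagonal); the symmetric
// form makes path costs invariant under start/stop reversal. The search
// stops at the first (minimum-cost) pixel of the stop region. Ties are
// resolved by linear pixel index so traces are deterministic.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cq_livewire")]]
List cq_livewire(NumericVector cost, int nr, int nc, int start,
                 LogicalVector stop) {
  const int n = nr * nc;
  const double SQ2 = std::sqrt(2.0);
  std::vector<double> dist(n, R_PosInf);
  std::vector<int> pred(n, -1);
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;
  dist[start] = 0.0;
  pq.push(Node(0.0, start));
  int goal = -1;
  while (!pq.empty()) {
    Node top = pq.top();
    pq.pop();
    int u = top.second;
    if (top.first > dist[u]) continue;
    if (stop[u]) { goal = u; break; }
    int c = u / nr, r = u % nr;
    for (int dc = -1; dc <= 1; ++dc) {
      int cc = c + dc;
      if (cc < 0 || cc >= nc) continue;
      for (int dr = -1; dr <= 1; ++dr) {
        if (!dr && !dc) continue;
        int rr = r + dr;
        if (rr < 0 || rr >= nr) continue;
        int v = cc * nr + rr;
        double w = 0.5 * (cost[u] + cost[v]) * ((dr && dc) ? SQ2 : 1.0);
        double nd = dist[u] + w;
        if (nd < dist[v]) {
          dist[v] = nd;
          pred[v] = u;
          pq.push(Node(nd, v));
        }
      }
    }
  }
  if (goal < 0)
    return List::create(_["found"] = false);
  std::vector<int> path;
  for (int v = goal; v >= 0; v = pred[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return List::create(_["found"] = true,
                      _["path"] = IntegerVector(path.begin(), path.end()),
                      _["cost"] = dist[goal]);
}

// ---------------------------------------------------------------------------
// Transport simulator event loop.
//
// The loop consumes R's global RNG (unif_rand / norm_rand) in a documented,
// fixed order so that the R reference implementation of the single events
// (attemptSignaling, insertCell, migrateCell, decayWnt iterated by simStep)
// produces bit-identical trajectories under the same seed:
//   per step, positions are visited in index order;
//   producer: 1 uniform (accept) [+ angle draw(s) + length draws on accept];
//   receiver: 1 uniform (insert accept) [+ 1 uniform donor choice],
//             1 uniform (migrate accept) [+ 1 uniform neighbour choice],
//             1 uniform (decay accept).
// ---------------------------------------------------------------------------

static double draw_angle(int angleDist, double kappa) {
  if (angleDist == 0) {             // uniform over the half-plane (+y)
    return M_PI * unif_rand();
  }
  // von Mises, mean pi/2 (into the tissue), Best-Fisher rejection
  double tau = 1.0 + std::sqrt(1.0 + 4.0 * kappa * kappa);
  double rho = (tau - std::sqrt(2.0 * tau)) / (2.0 * kappa);
  double r = (1.0 + rho * rho) / (2.0 * rho);
  double f;
  for (;;) {
    double u1 = unif_rand();
    double z = std::cos(M_PI * u1);
    f = (1.0 + r * z) / (r + z);
    double cc = kappa * (r - f);
    double u2 = unif_rand();
    if (cc * (2.0 - cc) - u2 > 0.0) break;
    if (std::log(cc / u2) + 1.0 - cc >= 0.0) break;
  }
  double u3 = unif_rand();
  double th = M_PI / 2.0 + ((u3 - 0.5 >= 0.0) ? 1.0 : -1.0) * std::acos(f);
  return th;
}

static double draw_length(double lmean, double lsd) {
  double L;
  do {
    L = lmean + lsd * norm_rand();
  } while (L <= 0.0);
  return L;
}

static int pick_index(int ncand) {        // uniform in 0..ncand-1
  int j = (int)(unif_rand() * ncand);
  if (j >= ncand) j = ncand - 1;
  return j;
}

// [[Rcpp::export(name = ".cq_sim_run")]]
List cq_sim_run(NumericMatrix pos, NumericVector marginDist,
                IntegerVector role0, NumericVector wnt0,
                IntegerMatrix neighbors, int nsteps, List par,
                bool keepLedger) {
  const int n = pos.nrow();
  const double pFilo = par["pFilo"], pInsert = par["pInsert"];
  const double pMigrate = par["pMigrate"], pDecay = par["pDecay"];
  const double lMean = par["lFiloMean"], lSd = par["lFiloSd"];
  const double radius = par["cellRadius"], tipTol = par["tipTol"];
  const double reseedTol = par["reseedTol"];
  const double depositAmount = par["depositAmount"];
  const double decayAmount = par["decayAmount"];
  const double kappa = par["angleKappa"];
  const int angleDist = par["angleDist"];   // 0 uniform-halfplane, 1 von Mises
  const int nbMax = neighbors.ncol();

  IntegerVector role = clone(role0);
  NumericVector wnt = clone(wnt0);
  double deposits = 0.0, insertGain = 0.0, decays = 0.0;
  int nSignal = 0, nDeposit = 0, nInsert = 0, nInsertSkipped = 0,
      nMigrate = 0, nDecay = 0;

  NumericMatrix ledger(keepLedger ? nsteps : 0, 4);
  std::vector<int> path;
  path.reserve(256);

  for (int s = 0; s < nsteps; ++s) {
    for (int i = 0; i < n; ++i) {
      int ri = role[i];
      if (ri == 0) continue;
      if (ri == 1) {                                    // producer
        if (unif_rand() < pFilo) {
          ++nSignal;
          double th = draw_angle(angleDist, kappa);
          double L = draw_length(lMean, lSd);
          double tx = pos(i, 0) + L * std::cos(th);
          double ty = pos(i, 1) + L * std::sin(th);
          // nearest receiver centre
          int best = -1;
          double bestd2 = R_PosInf;
          for (int j = 0; j < n; ++j) {
            if (role[j] != 2) continue;
            double dx = pos(j, 0) - tx, dy = pos(j, 1) - ty;
            double d2 = dx * dx + dy * dy;
            if (d2 < bestd2) { bestd2 = d2; best = j; }
          }
          if (best >= 0 &&
              std::fabs(std::sqrt(bestd2) - radius) <= tipTol) {
            wnt[best] += depositAmount;
            deposits += depositAmount;
            ++nDeposit;
          }
        }
      } else {                                          // receiver
        if (unif_rand() < pInsert) {
          // nearest empty position (tie -> smallest index)
          int e = -1;
          double bestd2 = R_PosInf;
          for (int j = 0; j < n; ++j) {
            if (role[j] != 0) continue;
            double dx = pos(j, 0) - pos(i, 0), dy = pos(j, 1) - pos(i, 1);
            double d2 = dx * dx + dy * dy;
            if (d2 < bestd2) { bestd2 = d2; e = j; }
          }
          if (e < 0) {
            ++nInsertSkipped;                           // full lattice
          } else {
            // greedy lattice path i -> e avoiding producer positions
            path.clear();
            path.push_back(i);
            int cur = i;
            bool ok = true;
            while (cur != e) {
              double dcur_x = pos(cur, 0) - pos(e, 0);
              double dcur_y = pos(cur, 1) - pos(e, 1);
              double dcur = dcur_x * dcur_x + dcur_y * dcur_y;
              int nxt = -1;
              double bd = dcur;
              for (int k = 0; k < nbMax; ++k) {
                int nb = neighbors(cur, k);
                if (nb == 0) break;
                int j = nb - 1;
                if (role[j] == 1) continue;             // never move producers
                double dx = pos(j, 0) - pos(e, 0);
                double dy = pos(j, 1) - pos(e, 1);
                double d2 = dx * dx + dy * dy;
                if (d2 < bd) { bd = d2; nxt = j; }
              }
              if (nxt < 0 || (int)path.size() > n) { ok = false; break; }
              path.push_back(nxt);
              cur = nxt;
            }
            if (!ok) {
              ++nInsertSkipped;
            } else {
              // shift contents outward along the path; path.front() empties
              for (size_t j = path.size() - 1; j >= 1; --j) {
                role[path[j]] = role[path[j - 1]];
                wnt[path[j]] = wnt[path[j - 1]];
              }
              int p0 = path[0];
              role[p0] = 0;
              wnt[p0] = 0.0;
              // duplicate a receiver at a similar margin distance
              double m0 = marginDist[p0];
              int ncand = 0;
              for (int j = 0; j < n; ++j)
                if (role[j] == 2 &&
                    std::fabs(marginDist[j] - m0) <= reseedTol)
                  ++ncand;
              double newWnt = 0.0;
              if (ncand > 0) {
                int want = pick_index(ncand);
                int seen = 0;
                for (int j = 0; j < n; ++j) {
                  if (role[j] == 2 &&
                      std::fabs(marginDist[j] - m0) <= reseedTol) {
                    if (seen == want) { newWnt = wnt[j]; break; }
                    ++seen;
                  }
                }
              }
              role[p0] = 2;
              wnt[p0] = newWnt;
              insertGain += newWnt;
              ++nInsert;
            }
          }
        }
        if (unif_rand() < pMigrate) {
          int cand[8], ncand = 0;
          for (int k = 0; k < nbMax; ++k) {
            int nb = neighbors(i, k);
            if (nb == 0) break;
            if (role[nb - 1] == 2) cand[ncand++] = nb - 1;
          }
          if (ncand > 0) {
            int j = cand[pick_index(ncand)];
            double tw = wnt[i]; wnt[i] = wnt[j]; wnt[j] = tw;
            ++nMigrate;
          }
        }
        if (unif_rand() < pDecay) {
          double dec = std::min(wnt[i], decayAmount);
          wnt[i] -= dec;
          decays += dec;
          ++nDecay;
        }
      }
    }
    if (keepLedger) {
      double tot = 0.0;
      for (int j = 0; j < n; ++j) if (role[j] == 2) tot += wnt[j];
      ledger(s, 0) = deposits;
      ledger(s, 1) = insertGain;
      ledger(s, 2) = decays;
      ledger(s, 3) = tot;
    }
  }

  return List::create(_["role"] = role, _["wnt"] = wnt,
    _["deposits"] = deposits, _["insertGain"] = insertGain,
    _["decays"] = decays, _["ledger"] = ledger,
    _["counts"] = IntegerVector::create(_["signal"] = nSignal,
      _["deposit"] = nDeposit, _["insert"] = nInsert,
      _["insertSkipped"] = nInsertSkipped, _["migrate"] = nMigrate,
      _["decay"] = nDecay));
}

// ---------------------------------------------------------------------------
// lsFCS particle simulation.
//
// Species of point emitters perform 2D Brownian motion on a periodic
// membrane strip (lateral u x axial v, box boxL x boxD, focus at the
// origin). Per scan line, the detected rate is
//   F_ch = sum_i bright_ch * exp(-2 u^2 / w0^2 - 2 v^2 / (S w0)^2),
// which is then spread across the scan-line pixels as a Gaussian membrane
// profile centred at center[t] (sd profileSdPx), background added, and
// shot noise applied per pixel.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cq_fcs_sim")]]
List cq_fcs_sim(int nLines, int nPix, NumericVector spD,
                IntegerVector spN, NumericVector brightG,
                NumericVector brightR, double w0, double S,
                double boxL, double boxD, double dt,
                NumericVector centerPx, double profileSdPx,
                double bgPerPixel, bool shotNoise) {
  const int nsp = spD.size();
  const double au = 2.0 / (w0 * w0);
  const double av = 2.0 / (S * w0 * S * w0);
  // negligible-weight cutoffs (weight < ~1e-9)
  const double cutU = std::sqrt(20.0 / au), cutV = std::sqrt(20.0 / av);

  int ntot = 0;
  for (int s = 0; s < nsp; ++s) ntot += spN[s];
  std::vector<double> u(ntot), v(ntot);
  std::vector<double> sig(nsp);
  for (int s = 0; s < nsp; ++s) sig[s] = std::sqrt(2.0 * spD[s] * dt);
  {
    int k = 0;
    for (int s = 0; s < nsp; ++s)
      for (int p = 0; p < spN[s]; ++p, ++k) {
        u[k] = (unif_rand() - 0.5) * boxL;
        v[k] = (unif_rand() - 0.5) * boxD;
      }
  }

  NumericVector Fg(nLines), Fr(nLines);
  for (int t = 0; t < nLines; ++t) {
    int k = 0;
    for (int s = 0; s < nsp; ++s) {
      double W = 0.0;
      const double ss = sig[s];
      for (int p = 0; p < spN[s]; ++p, ++k) {
        if (ss > 0.0) {
          u[k] += ss * norm_rand();
          v[k] += ss * norm_rand();
          if (u[k] > boxL / 2) u[k] -= boxL;
          else if (u[k] < -boxL / 2) u[k] += boxL;
          if (v[k] > boxD / 2) v[k] -= boxD;
          else if (v[k] < -boxD / 2) v[k] += boxD;
        }
        double uu = u[k], vv = v[k];
        if (std::fabs(uu) < cutU && std::fabs(vv) < cutV)
          W += std::exp(-au * uu * uu - av * vv * vv);
      }
      Fg[t] += brightG[s] * W;
      Fr[t] += brightR[s] * W;
    }
  }

  NumericMatrix imgG(nLines, nPix), imgR(nLines, nPix);
  const double den = 2.0 * profileSdPx * profileSdPx;
  std::vector<double> prof(nPix);
  for (int t = 0; t < nLines; ++t) {
    double c = centerPx[t], Z = 0.0;
    for (int x = 0; x < nPix; ++x) {
      double d = (x + 1) - c;                 // 1-based pixel centres
      prof[x] = std::exp(-d * d / den);
      Z += prof[x];
    }
    for (int x = 0; x < nPix; ++x) {
      double mg = Fg[t] * prof[x] / Z + bgPerPixel;
      double mr = Fr[t] * prof[x] / Z + bgPerPixel;
      if (shotNoise) {
        imgG(t, x) = R::rpois(mg);
        imgR(t, x) = R::rpois(mr);
      } else {
        imgG(t, x) = mg;
        imgR(t, x) = mr;
      }
    }
  }
  return List::create(_["green"] = imgG, _["red"] = imgR,
                      _["rateGreen"] = Fg, _["rateRed"] = Fr);
}
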