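#include <Rcpp.h>
#include <climits>
#include <string>
#include <vector>
using namespace Rcpp;

// Three-part decomposition of a junction-spanning read.
//
// The read is split into a left part read[0,i), an optional unmapped middle
// insertion read[i,j) (j >= i), and a right part read[j,R).  The left part is
// aligned to the upstream arm and the right part to the downstream arm; each
// part is global in the read and local in the arm (both arm ends free), with
// affine gaps inside the arms.  The junction-proximal free arm ends are
// reported as del_up / del_down.  When j < i the two parts overlap in the
// read by i - j bases (bounded by max_overlap); overlap bases are scored in
// both parts, which is what lets a single retained copy of junction-flanking
// homology (a staggered-cut overhang or an MMEJ microhomology) count for
// both arms.

namespace {

const int NEG = INT_MIN / 4;

inline int sub_score(char a, char b, int match, int mismatch) {
  // N never counts as a match
  if (a == 'N' || b == 'N') return mismatch;
  return (a == b) ? match : mismatch;
}

struct Profile {
  // indexed by read-prefix length r = 0..R
  std::vector<int> score;     // best fit-alignment score over all arm ends
  std::vector<int> arm_end;   // arm end (exclusive) of that optimum; ties -> largest
  std::vector<int> arm_start; // arm start (origin) of that optimum
};

// Fit alignment of every prefix of `read` against substrings of `arm`:
// the prefix is aligned globally, the arm start and end are free.  A gap of
// length k costs gap_open + k * gap_ext (costs passed as positive numbers).
Profile fit_profile(const std::string& read, const std::string& arm,
                    int match, int mismatch, int gap_open, int gap_ext) {
  const int R = (int)read.size();
  const int m = (int)arm.size();

  Profile out;
  out.score.assign(R + 1, NEG);
  out.arm_end.assign(R + 1, 0);
  out.arm_start.assign(R + 1, 0);

  // rolling rows over arm position u; states M (diagonal), X (arm base vs
  // gap), Y (read base vs gap); *_o carries the arm-start origin of the path
  std::vector<int> M(R + 1, NEG), X(R + 1, NEG), Y(R + 1, NEG);
  std::vector<int> Mo(R + 1, 0), Xo(R + 1, 0), Yo(R + 1, 0);
  std::vector<int> Mp(R + 1, NEG), Xp(R + 1, NEG), Yp(R + 1, NEG);
  std::vector<int> Mpo(R + 1, 0), Xpo(R + 1, 0), Ypo(R + 1, 0);

  for (int u = 0; u <= m; ++u) {
    for (int r = 0; r <= R; ++r) {
      int m_ = NEG, x_ = NEG, y_ = NEG, mo = 0, xo = 0, yo = 0;
      if (r >= 1) {
        if (u >= 1) {
          // M: consume arm[u-1] and read[r-1]; predecessor H[u-1][r-1]
          int hp, ho;
          if (r - 1 == 0) {
            hp = 0; ho = u - 1; // free start in arm
          } else {
            hp = Mp[r - 1]; ho = Mpo[r - 1];
            if (Xp[r - 1] > hp) { hp = Xp[r - 1]; ho = Xpo[r - 1]; }
            if (Yp[r - 1] > hp) { hp = Yp[r - 1]; ho = Ypo[r - 1]; }
          }
          if (hp > NEG) {
            m_ = hp + sub_score(arm[u - 1], read[r - 1], match, mismatch);
            mo = ho;
          }
          // X: consume arm[u-1] against a gap (same r); no X at r == 0
          // (leading arm bases are skipped for free instead)
          int h1 = NEG, h1o = 0;
          if (Mp[r] > h1) { h1 = Mp[r]; h1o = Mpo[r]; }
          if (Yp[r] > h1) { h1 = Yp[r]; h1o = Ypo[r]; }
          if (h1 > NEG) { x_ = h1 - gap_open - gap_ext; xo = h1o; }
          if (Xp[r] > NEG && Xp[r] - gap_ext > x_) { x_ = Xp[r] - gap_ext; xo = Xpo[r]; }
        }
        // Y: consume read[r-1] against a gap (same u); valid for any u
        {
          int hp, ho;
          if (r - 1 == 0) {
            hp = 0; ho = u;
          } else {
            hp = M[r - 1]; ho = Mo[r - 1];
            if (X[r - 1] > hp) { hp = X[r - 1]; ho = Xo[r - 1]; }
          }
          if (hp > NEG) { y_ = hp - gap_open - gap_ext; yo = ho; }
          if (Y[r - 1] > NEG && Y[r - 1] - gap_ext > y_) {
            y_ = Y[r - 1] - gap_ext; yo = Yo[r - 1];
          }
        }
      }
      M[r] = m_; Mo[r] = mo;
      X[r] = x_; Xo[r] = xo;
      Y[r] = y_; Yo[r] = yo;

      // candidate: alignment of read[0,r) ending at arm position u
      int h, ho;
      if (r == 0) {
        h = 0; ho = u;
      } else {
        // ending in X (trailing arm gap) is never useful with free arm ends
        h = m_; ho = mo;
        if (y_ > h) { h = y_; ho = yo; }
      }
      if (h > NEG && h >= out.score[r]) { // ties -> larger arm_end
        out.score[r] = h;
        out.arm_end[r] = u;
        out.arm_start[r] = ho;
      }
    }
    std::swap(M, Mp); std::swap(X, Xp); std::swap(Y, Yp);
    std::swap(Mo, Mpo); std::swap(Xo, Xpo); std::swap(Yo, Ypo);
  }
  return out;
}

} // namespace

// [[Rcpp::export]]
List split_align_cpp(std::string read, std::string up, std::string down,
                     int match, int mismatch, int gap_open, int gap_ext,
                     int ins_penalty, int max_overlap, int min_anchor) {
  const int R = (int)read.size();
  const int Lu = (int)up.size();
  const int Ld = (int)down.size();
  if (R < 2 * min_anchor) stop("read too short");

  Profile L = fit_profile(read, up, match, mismatch, gap_open, gap_ext);

  std::string read_rev(read.rbegin(), read.rend());
  std::string down_rev(down.rbegin(), down.rend());
  Profile Rt = fit_profile(read_rev, down_rev, match, mismatch, gap_open, gap_ext);

  // combine: maximize L[i] + Rt[R-j] - ins_penalty * max(0, j - i)
  // subject to min_anchor <= i, j <= R - min_anchor, i - j <= max_overlap.
  // Ties: smaller middle, then smaller del_up+del_down, then larger overlap,
  // then leftmost split.
  long best = LONG_MIN;
  int bi = -1, bj = -1, bmid = 0, bdel = 0, bov = 0;
  for (int i = min_anchor; i <= R; ++i) {
    if (L.score[i] <= NEG) continue;
    int del_up = Lu - L.arm_end[i];
    int jlo = i - max_overlap; if (jlo < 0) jlo = 0;
    for (int j = jlo; j <= R - min_anchor; ++j) {
      int t = R - j;
      if (Rt.score[t] <= NEG) continue;
      int mid = j > i ? (j - i) : 0;
      int ov = j < i ? (i - j) : 0;
      long sc = (long)L.score[i] + Rt.score[t] - (long)ins_penalty * mid;
      int del = del_up + (Ld - Rt.arm_end[t]);
      bool take = false;
      if (sc > best) take = true;
      else if (sc == best) {
        if (mid < bmid) take = true;
        else if (mid == bmid) {
          if (del < bdel) take = true;
          else if (del == bdel) {
            if (ov > bov) take = true;
            else if (ov == bov && i < bi) take = true;
          }
        }
      }
      if (take) {
        best = sc; bi = i; bj = j; bmid = mid; bdel = del; bov = ov;
      }
    }
  }
  if (bi < 0) stop("no valid decomposition");

  int tl = R - bj;
  int down_start = Ld - Rt.arm_end[tl];
  int down_end = Ld - Rt.arm_start[tl];

  return List::create(
    _["score"] = (double)best,
    _["i"] = bi,
    _["j"] = bj,
    _["overlap_len"] = bov,
    _["del_up"] = Lu - L.arm_end[bi],
    _["del_down"] = Ld - Rt.arm_end[tl],
    _["up_start"] = L.arm_start[bi],
    _["up_end"] = L.arm_end[bi],
    _["down_start"] = down_start,
    _["down_end"] = down_end,
    _["left_score"] = L.score[bi],
    _["right_score"] = Rt.score[tl]);
}
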