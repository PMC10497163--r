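// Fast rollouts of the nearest-neighbour heuristic policy on the
// tile-revealing task: click uniformly among covered tiles 4-adjacent to a
// revealed red tile (uniform among all covered tiles when that set is
// empty), until every red tile is revealed.  Returns the per-trial count of
// blue tiles revealed.
#include <Rcpp.h>
#include <random>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerVector cpp_heuristic_rollouts(IntegerVector board, int n_trials,
                                     int start_tile, int seed) {
  const int n = board.size();
  const int side = static_cast<int>(std::lround(std::sqrt(double(n))));
  if (side * side != n) stop("board length must be a perfect square");
  if (start_tile < 1 || start_tile > n || board[start_tile - 1] != 1)
    stop("start_tile must index a red tile");

  // column-major neighbour lists
  std::vector<std::vector<int>> nb(n);
  for (int i = 0; i < n; ++i) {
    int r = i % side, c = i / side;
    if (r > 0) nb[i].push_back(i - 1);
    if (r < side - 1) nb[i].push_back(i + 1);
    if (c > 0) nb[i].push_back(i - side);
    if (c < side - 1) nb[i].push_back(i + side);
  }
  int total_red = 0;
  for (int i = 0; i < n; ++i) total_red += board[i];

  std::mt19937_64 rng(static_cast<uint64_t>(seed));
  IntegerVector blue_counts(n_trials);
  std::vector<char> revealed(n);
  std::vector<int> cand;
  cand.reserve(n);

  for (int trial = 0; trial < n_trials; ++trial) {
    std::fill(revealed.begin(), revealed.end(), 0);
    revealed[start_tile - 1] = 1;
    int red_found = 1, blue = 0;
    while (red_found < total_red) {
      cand.clear();
      for (int i = 0; i < n; ++i) {
        if (revealed[i]) continue;
        for (int j : nb[i]) {
          if (revealed[j] && board[j] == 1) { cand.push_back(i); break; }
        }
      }
      if (cand.empty()) {
        for (int i = 0; i < n; ++i) if (!revealed[i]) cand.push_back(i);
      }
      int pick = cand[std::uniform_int_distribution<int>(0, cand.size() - 1)(rng)];
      revealed[pick] = 1;
      if (board[pick] == 1) ++red_found; else ++blue;
    }
    blue_counts[trial] = blue;
  }
  return blue_counts;
}
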